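#' Layout data for the allele lollipop plot
#'
#' One row per allele/variant pair: the genomic extent of each variant in an
#' allele, the allele's row on the y axis, and its read support. Exposed
#' separately so the plot layout can be tested without a graphics device.
#'
#' @param report a `reversion_report`
#' @return data.frame with `allele`, `key`, `xstart`, `xend` (1-based
#'   genomic), `kind`, `n_support`, `vaf`, `homopolymer_flag`
#' @export
allele_map_data <- function(report) {
  ctx <- report$ctx
  rows <- list()
  for (i in seq_along(report$alleles)) {
    a <- report$alleles[[i]]
    v <- a$variants
    for (k in seq_len(nrow(v))) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele = i, key = a$key,
        xstart = v$pos[k] + ctx$window$start + 1L,
        xend = v$pos[k] + ctx$window$start + max(nchar(v$ref[k]), 1L),
        kind = v$kind[k], n_support = a$n_support, vaf = a$vaf,
        homopolymer_flag = a$homopolymer_flag,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(allele = integer(), key = character(),
                      xstart = integer(), xend = integer(),
                      kind = character(), n_support = integer(),
                      vaf = numeric(), homopolymer_flag = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Plot a lollipop-style reversion allele map
#'
#' X axis: genomic position over the alignment window; one marker row per
#' allele spanning its variant extents, labelled with read support; the
#' pathogenic variant is highlighted as a vertical line. An empty report
#' produces annotated empty axes. Output format follows the file extension
#' (`.png`, `.svg`, `.pdf`); PNG falls back to cairo where needed.
#'
#' @param report a `reversion_report`
#' @param out_path image file to create; `NULL` draws on the current device
#' @return the layout data.frame from [allele_map_data()], invisibly
#' @export
plot_allele_map <- function(report, out_path = NULL) {
  if (!is.null(out_path)) {
    ext <- tolower(tools::file_ext(out_path))
    switch(ext,
      png = grDevices::png(out_path, width = 900, height = 500,
                           type = if (capabilities("cairo")) "cairo"
                                  else getOption("bitmapType")),
      svg = grDevices::svg(out_path, width = 9, height = 5),
      pdf = grDevices::pdf(out_path, width = 9, height = 5),
      stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ctx <- report$ctx
  dat <- allele_map_data(report)
  xlim <- c(ctx$window$start + 1L, ctx$window$end)
  n <- length(report$alleles)
  path_x <- ctx$edit$start + ctx$window$start + 1L

  graphics::plot(NA, xlim = xlim, ylim = c(0, max(n, 1) + 1),
                 xlab = sprintf("position on %s", ctx$window$chrom),
                 ylab = "reversion allele", yaxt = "n",
                 main = sprintf("Reversion alleles near %s",
                                report$variant$id))
  graphics::abline(v = path_x, col = "red", lwd = 2, lty = 2)
  graphics::mtext("pathogenic", side = 3, at = path_x, col = "red",
                  cex = 0.8)
  if (n == 0L) {
    graphics::text(mean(xlim), 0.5, "no reversion alleles detected",
                   col = "grey40")
  } else {
    for (i in seq_len(n)) {
      d <- dat[dat$allele == i, , drop = FALSE]
      y <- n - i + 1
      graphics::segments(min(d$xstart), y, max(d$xend), y, col = "grey70")
      cx <- ifelse(d$kind == "INS", d$xstart, (d$xstart + d$xend) / 2)
      pch <- ifelse(d$kind == "DEL", 15, ifelse(d$kind == "INS", 17, 16))
      graphics::points(cx, rep(y, nrow(d)), pch = pch,
                       cex = 0.8 + log10(d$n_support[1] + 1),
                       col = ifelse(d$homopolymer_flag, "orange", "steelblue"))
      graphics::text(xlim[2], y, sprintf("n=%d", d$n_support[1]),
                     pos = 2, cex = 0.7)
    }
    graphics::axis(2, at = rev(seq_len(n)), labels = seq_len(n), las = 1,
                   cex.axis = 0.7)
  }
  invisible(dat)
}
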