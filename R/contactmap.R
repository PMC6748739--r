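# Shared heat-map renderer: rows top-to-bottom in matrix order, colour
# monotone in CSA, zero mapped to the low end of the scale.
.draw_contact_map <- function(m, palette = c("blue", "red"),
                              max_labels = 40L, main = NULL) {
  ramp <- colorRampPalette(palette)(256L)
  zmax <- max(m, 1e-12)
  op <- par(mar = c(7, 7, 3, 2))
  on.exit(par(op))
  image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
        z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
        zlim = c(0, zmax), col = ramp, axes = FALSE, xlab = "", ylab = "",
        main = main)
  thin <- function(k) unique(round(seq(1L, k,
                                       length.out = min(k, max_labels))))
  ix <- thin(ncol(m)); iy <- thin(nrow(m))
  axis(1, at = ix, labels = colnames(m)[ix], las = 2, cex.axis = 0.55)
  axis(2, at = nrow(m) + 1L - iy, labels = rownames(m)[iy], las = 2,
       cex.axis = 0.55)
  box()
}

#' Render a contact-matrix TSV as a heat-map image
#'
#' Reads a matrix written by [write_matrix_tsv()] and renders it with
#' rows and columns in file order; cell colour is monotone in the contact
#' area with 0 at the low end of the scale (default blue, low, to red,
#' high).  The TSV is opened read-only and never modified.
#'
#' @param tsv_path Input matrix TSV.
#' @param out_path Output image path; its extension may also pick the
#'   format.
#' @param format `"png"` or `"svg"`.
#' @param palette Two or more colours, low to high.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @param max_labels Largest number of axis labels drawn per side.
#' @return `out_path`, invisibly.
#' @export
render_contact_map <- function(tsv_path, out_path,
                               format = c("auto", "png", "svg"),
                               palette = c("blue", "red"),
                               width = NULL, height = NULL,
                               max_labels = 40L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(out_path))
    format <- if (ext == "svg") "svg" else "png"
  }
  m <- read_matrix_tsv(tsv_path)
  if (format == "png") {
    png(out_path, width = if (is.null(width)) 900 else width,
        height = if (is.null(height)) 900 else height, res = 120)
  } else {
    svg(out_path, width = if (is.null(width)) 8 else width,
        height = if (is.null(height)) 8 else height)
  }
  on.exit(dev.off())
  .draw_contact_map(m, palette = palette, max_labels = max_labels,
                    main = basename(tsv_path))
  invisible(out_path)
}
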