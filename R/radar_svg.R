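# fixed-format number for deterministic SVG output
.fmt <- function(x) sprintf("%.4f", x)

#' Write a radar (star) chart of IBR scores as SVG
#'
#' One equally spaced axis per biomarker, radial length = S, one closed
#' polygon per group. A dashed black polygon marks the locus where the
#' signed score Z equals 0 on every axis (the baseline for the
#' standardized values); under the global min scope this locus is a
#' circle. The SVG is emitted directly with fixed numeric formatting so
#' identical results produce byte-identical files.
#'
#' @param result an \code{ibr_result}.
#' @param path output .svg path.
#' @param size canvas edge in pixels.
#' @return \code{path}, invisibly.
#' @export
write_radar_svg <- function(result, path, size = 480) {
  stopifnot(inherits(result, "ibr_result"))
  S <- result$S
  k <- ncol(S)
  angles <- 2 * pi * (seq_len(k) - 1) / k
  r_zero <- abs(apply(result$Z, 2, min))        # radius of the Z = 0 locus
  if (result$min_scope == "global") r_zero <- rep(abs(min(result$Z)), k)
  rmax <- max(S, r_zero, 1e-9)
  cx <- size / 2; cy <- size / 2
  scale <- 0.40 * size / rmax
  px <- function(r, a) c(cx + scale * r * cos(a), cy - scale * r * sin(a))
  poly_points <- function(r) {
    paste(vapply(seq_len(k), function(i) {
      xy <- px(r[i], angles[i]); paste(.fmt(xy[1]), .fmt(xy[2]), sep = ",")
    }, character(1)), collapse = " ")
  }
  cols <- rep(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                "#66a61e", "#e6ab02"), length.out = nrow(S))

  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   size, size, size, size),
           sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))
  for (i in seq_len(k)) {                       # axes + labels
    tip <- px(rmax, angles[i])
    lab <- px(rmax * 1.08, angles[i])
    out <- c(out,
             sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#bbbbbb" stroke-width="1"/>',
                     .fmt(cx), .fmt(cy), .fmt(tip[1]), .fmt(tip[2])),
             sprintf('<text x="%s" y="%s" font-size="11" text-anchor="middle" fill="#333333">%s</text>',
                     .fmt(lab[1]), .fmt(lab[2]), colnames(S)[i]))
  }
  out <- c(out,                                  # zero-axis reference
           sprintf('<polygon points="%s" fill="none" stroke="black" stroke-width="1" stroke-dasharray="5,4"/>',
                   poly_points(r_zero)))
  for (g in seq_len(nrow(S))) {
    out <- c(out,
             sprintf('<polygon points="%s" fill="%s" fill-opacity="0.15" stroke="%s" stroke-width="2"/>',
                     poly_points(S[g, ]), cols[g], cols[g]),
             sprintf('<text x="10" y="%d" font-size="12" fill="%s">%s (IBR = %s)</text>',
                     16 * g, cols[g], rownames(S)[g],
                     .fmt(result$ibr_index[g])))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
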