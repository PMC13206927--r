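#' Relative quantification by the 2^-ddCt method
#'
#' Fold change of a target transcript in a treated condition relative to a
#' control condition, each normalized to a reference gene (e.g. beta-actin):
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#'        (Ct_target,control - Ct_ref,control); fold change = 2^-ddCt.
#'
#' @param ct_target_treated,ct_reference_treated,ct_target_control,ct_reference_control
#'   cycle-threshold values (vectorized).
#' @return fold change, dimensionless.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  ct <- c(ct_target_treated, ct_reference_treated,
          ct_target_control, ct_reference_control)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2 ^ (-ddct)
}

#' Build a biomarker panel from a replicate-level table
#'
#' Collapses replicates to group-level means (the X matrix of the IBR
#' construction) in the supplied group and biomarker orders.
#'
#' @param replicate_table \code{data.frame} with columns \code{group},
#'   \code{replicate}, \code{biomarker}, \code{value}.
#' @param directions named character vector or two-column
#'   \code{data.frame} (biomarker, direction) with values \code{"up"} or
#'   \code{"down"}: the expected response direction upon treatment.
#' @param group_order,biomarker_order orderings; default = order of first
#'   appearance in the table.
#' @return a \code{biomarker_panel}: list with \code{groups},
#'   \code{biomarkers}, \code{directions}, \code{X} (group x biomarker
#'   matrix of means), \code{replicates} (the source table).
#' @export
build_panel <- function(replicate_table, directions,
                        group_order = NULL, biomarker_order = NULL) {
  tb <- as.data.frame(replicate_table)
  need <- c("group", "biomarker", "value")
  if (!all(need %in% names(tb)))
    stop("replicate table must have columns group, biomarker, value")
  if (is.data.frame(directions))
    directions <- stats::setNames(as.character(directions[[2]]),
                                  as.character(directions[[1]]))
  if (is.null(group_order)) group_order <- unique(as.character(tb$group))
  if (is.null(biomarker_order)) biomarker_order <- unique(as.character(tb$biomarker))
  if (length(group_order) < 2L) stop("a panel needs at least 2 groups")
  if (length(biomarker_order) < 2L) stop("a panel needs at least 2 biomarkers")
  missing_dir <- setdiff(biomarker_order, names(directions))
  if (length(missing_dir))
    stop("no direction flag for biomarker(s): ",
         paste(missing_dir, collapse = ", "))
  bad <- setdiff(directions[biomarker_order], c("up", "down"))
  if (length(bad))
    stop("unknown direction label(s): ", paste(unique(bad), collapse = ", "))

  X <- matrix(NA_real_, nrow = length(group_order),
              ncol = length(biomarker_order),
              dimnames = list(group_order, biomarker_order))
  for (g in group_order) for (b in biomarker_order) {
    v <- tb$value[tb$group == g & tb$biomarker == b]
    if (length(v)) X[g, b] <- mean(v)
  }
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    miss <- paste0("(", rownames(X)[idx[, 1]], ", ",
                   colnames(X)[idx[, 2]], ")")
    stop("no replicates for cell(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(X))) stop("non-finite replicate values in the table")
  structure(list(groups = group_order, biomarkers = biomarker_order,
                 directions = directions[biomarker_order], X = X,
                 replicates = tb),
            class = "biomarker_panel")
}

#' Build a panel directly from a group-mean matrix
#'
#' @param X numeric matrix, groups in rows, biomarkers in columns, with
#'   dimnames.
#' @param directions as in [build_panel()].
#' @return a \code{biomarker_panel}.
#' @export
panel_from_means <- function(X, directions) {
  stopifnot(is.matrix(X), !is.null(rownames(X)), !is.null(colnames(X)))
  long <- data.frame(group = rep(rownames(X), ncol(X)),
                     replicate = 1L,
                     biomarker = rep(colnames(X), each = nrow(X)),
                     value = as.vector(X), stringsAsFactors = FALSE)
  build_panel(long, directions, rownames(X), colnames(X))
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("biomarker_panel: ", length(x$groups), " groups x ",
      length(x$biomarkers), " biomarkers\n", sep = "")
  print(x$X)
  invisible(x)
}

#' Standardize a panel's group means
#'
#' Y[g, b] = (X[g, b] - m_b) / s_b where m_b and s_b are the mean and
#' standard deviation of biomarker b across the panel's groups. The SD
#' flavor is explicit: \code{"sample"} (n - 1 denominator, default) or
#' \code{"population"} (n denominator). A biomarker constant across
#' groups (s = 0) yields a zero Y column with a warning rather than an
#' error.
#'
#' @param panel a \code{biomarker_panel}.
#' @param sd_mode \code{"sample"} or \code{"population"}.
#' @return list with \code{Y} (matrix), \code{m}, \code{s} (named per
#'   biomarker).
#' @export
standardize <- function(panel, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  X <- panel$X
  G <- nrow(X)
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (sd_mode == "population") s <- s * sqrt((G - 1) / G)
  Y <- X
  for (b in seq_len(ncol(X))) {
    if (s[b] == 0) {
      warning("biomarker '", colnames(X)[b],
              "' is constant across groups; standardized scores set to 0")
      Y[, b] <- 0
    } else {
      Y[, b] <- (X[, b] - m[b]) / s[b]
    }
  }
  list(Y = Y, m = m, s = s)
}

#' Apply response-direction signs to standardized scores
#'
#' Z = +Y for biomarkers that go up upon treatment, -Y for those that go
#' down, so that larger Z always means a larger treatment response.
#'
#' @param Y standardized matrix (groups x biomarkers).
#' @param directions named character vector, \code{"up"} or \code{"down"}
#'   per biomarker column of Y.
#' @return Z matrix.
#' @export
apply_direction <- function(Y, directions) {
  d <- directions[colnames(Y)]
  if (anyNA(d))
    stop("no direction for biomarker(s): ",
         paste(colnames(Y)[is.na(d)], collapse = ", "))
  bad <- setdiff(d, c("up", "down"))
  if (length(bad)) stop("unknown direction label(s): ",
                        paste(unique(bad), collapse = ", "))
  sgn <- ifelse(d == "up", 1, -1)
  sweep(Y, 2, sgn, `*`)
}

#' Translate signed scores to non-negative radar radii
#'
#' S = Z + |min(Z)|, with min(Z) taken per biomarker across groups by
#' default (\code{min_scope = "biomarker"}) or over the whole matrix
#' (\code{"global"}). |min(Z)| is added literally even when min(Z) > 0,
#' so S = 0 for the minimizing group only when min(Z) <= 0 — which is
#' guaranteed under the per-biomarker scope because Y columns are
#' centered.
#'
#' @param Z signed standardized matrix.
#' @param min_scope \code{"biomarker"} or \code{"global"}.
#' @return S matrix, all entries >= 0 when derived from centered Y.
#' @export
translate_scores <- function(Z, min_scope = c("biomarker", "global")) {
  min_scope <- match.arg(min_scope)
  if (any(!is.finite(Z))) stop("Z must be finite")
  if (min_scope == "global") {
    Z + abs(min(Z))
  } else {
    sweep(Z, 2, abs(apply(Z, 2, min)), `+`)
  }
}

#' Star-polygon area of one group's scores
#'
#' Biomarkers sit on equally spaced radar axes (axis i at angle
#' 2*pi*(i-1)/k); the index is the area of the closed polygon through the
#' points at radius S_i, i.e. the sum of adjacent-spoke triangles
#' S_i * S_{i+1} * sin(2*pi/k) / 2 with wraparound.
#'
#' @param S_row non-negative scores, in axis order.
#' @return area (dimensionless).
#' @export
star_area <- function(S_row) {
  k <- length(S_row)
  if (k < 2L) stop("at least 2 biomarkers are required")
  s_next <- c(S_row[-1], S_row[1])
  sum(S_row * s_next) * sin(2 * pi / k) / 2
}

#' Compute the Integrated Biomarker Response for a panel
#'
#' Chains standardization, direction signing, min-translation and
#' star-area per group. Higher index = larger overall response (for a
#' toxicant battery, more severe damage).
#'
#' @param panel a \code{biomarker_panel}.
#' @param sd_mode SD flavor for [standardize()].
#' @param min_scope scope of the min in [translate_scores()].
#' @return an \code{ibr_result}: list with \code{Y}, \code{Z}, \code{S},
#'   \code{m}, \code{s}, \code{star_coordinates} (per group: data.frame
#'   biomarker, angle, radius), \code{ibr_index} (named per group),
#'   \code{sd_mode}, \code{min_scope}.
#' @export
compute_ibr <- function(panel, sd_mode = c("sample", "population"),
                        min_scope = c("biomarker", "global")) {
  sd_mode <- match.arg(sd_mode)
  min_scope <- match.arg(min_scope)
  stopifnot(inherits(panel, "biomarker_panel"))
  std <- standardize(panel, sd_mode)
  Z <- apply_direction(std$Y, panel$directions)
  S <- translate_scores(Z, min_scope)
  k <- ncol(S)
  angles <- 2 * pi * (seq_len(k) - 1) / k
  coords <- lapply(rownames(S), function(g) {
    data.frame(biomarker = colnames(S), angle = angles,
               radius = unname(S[g, ]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(coords) <- rownames(S)
  idx <- apply(S, 1, star_area)
  structure(list(Y = std$Y, Z = Z, S = S, m = std$m, s = std$s,
                 star_coordinates = coords, ibr_index = idx,
                 sd_mode = sd_mode, min_scope = min_scope),
            class = "ibr_result")
}

#' @export
print.ibr_result <- function(x, ...) {
  cat("ibr_result (", x$sd_mode, " SD, ", x$min_scope, " min):\n", sep = "")
  print(round(x$ibr_index, 4))
  invisible(x)
}

#' Infer response directions from group means
#'
#' Optional helper: direction = sign of (mean over treated groups -
#' control mean) per biomarker, with the control group named explicitly.
#' Inferences are reported via a message.
#'
#' @param panel a \code{biomarker_panel} (directions ignored).
#' @param control label of the control group.
#' @return named character vector of "up"/"down".
#' @export
infer_directions <- function(panel, control) {
  X <- panel$X
  if (!control %in% rownames(X)) stop("unknown control group: ", control)
  treated <- setdiff(rownames(X), control)
  d <- ifelse(colMeans(X[treated, , drop = FALSE]) >= X[control, ],
              "up", "down")
  message("inferred directions: ",
          paste(colnames(X), d, sep = "=", collapse = ", "))
  d
}

# circular orderings of 1..k, unique up to rotation and reflection
.circular_orders <- function(k) {
  if (k <= 3L) return(list(seq_len(k)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rest <- perms(2:k)
  keep <- Filter(function(p) p[1] < p[length(p)], rest)  # drop reflections
  lapply(keep, function(p) c(1L, p))
}

#' Sensitivity of the IBR index to biomarker axis order
#'
#' The star area depends on which biomarkers sit on adjacent axes. This
#' reports the spread of the index over axis orderings: exhaustive over
#' all circular orders (up to rotation/reflection) when k <= 6, otherwise
#' over \code{n_permutations} random orderings drawn with \code{seed}.
#'
#' @param result an \code{ibr_result}.
#' @param n_permutations orderings to sample when k > 6.
#' @param seed RNG seed for sampling.
#' @return list with \code{summary} (data.frame: group, min, median, max,
#'   n_orderings) and \code{exhaustive} (logical).
#' @export
order_sensitivity <- function(result, n_permutations = 100, seed = 1) {
  stopifnot(inherits(result, "ibr_result"), n_permutations >= 1)
  S <- result$S
  k <- ncol(S)
  if (k <= 6L) {
    orders <- .circular_orders(k)
    exhaustive <- TRUE
  } else {
    orders <- with_seed(seed, replicate(n_permutations, sample.int(k),
                                        simplify = FALSE))
    exhaustive <- FALSE
  }
  vals <- sapply(orders, function(o) apply(S[, o, drop = FALSE], 1, star_area))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(rownames(S)))
  summ <- data.frame(group = rownames(S),
                     min = apply(vals, 1, min),
                     median = apply(vals, 1, stats::median),
                     max = apply(vals, 1, max),
                     n_orderings = length(orders),
                     row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summ, exhaustive = exhaustive)
}
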