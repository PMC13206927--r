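#' Load a GMT term annotation
#'
#' Standard tab-separated GMT: field 1 = term id, field 2 = description,
#' fields 3+ = member genes. Genes are normalized (uppercase, trimmed,
#' deduplicated within a term); terms left with zero genes are dropped.
#' The universe defaults to the union of all term genes unless overridden.
#'
#' @param path GMT file path.
#' @param universe optional \code{gene_set} overriding the default
#'   universe.
#' @return a \code{term_annotation}: list with \code{terms} (named list of
#'   \code{list(description, genes)}) and \code{universe} (a
#'   \code{gene_set}).
#' @export
load_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    genes <- normalize_symbols(f[-(1:2)])$symbols
    if (length(genes) == 0L) next
    terms[[trimws(f[1])]] <- list(description = f[2], genes = genes)
  }
  if (is.null(universe)) {
    universe <- normalize_symbols(unlist(lapply(terms, `[[`, "genes")),
                                  name = "annotation_universe")
  } else {
    stopifnot(inherits(universe, "gene_set"))
    # restrict terms to the declared universe
    terms <- lapply(terms, function(t) {
      t$genes <- intersect(t$genes, universe$symbols); t
    })
    terms <- Filter(function(t) length(t$genes) > 0L, terms)
  }
  structure(list(terms = terms, universe = universe),
            class = "term_annotation")
}

#' @export
print.term_annotation <- function(x, ...) {
  cat("term_annotation: ", length(x$terms), " terms over a universe of ",
      length(x$universe$symbols), " genes\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of p_(j) * m / j (sorted order), clipped to 1,
#' returned in the original order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Over-representation analysis of a query set
#'
#' For each term, tests whether the query hits the term more often than
#' expected under hypergeometric sampling from the annotation universe
#' (one-sided, upper tail). Query genes absent from the universe are
#' dropped before testing but reported via the \code{coverage} attribute.
#' Rows are sorted by ascending p-value, ties broken lexicographically by
#' term id; q-values are Benjamini-Hochberg across all returned terms.
#'
#' @param query a \code{gene_set}.
#' @param annotation a \code{term_annotation}.
#' @return \code{data.frame} with columns \code{term_id},
#'   \code{description}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p_value}, \code{q_value}; attribute \code{coverage} = fraction
#'   of query genes found in the universe.
#' @export
run_ora <- function(query, annotation) {
  stopifnot(inherits(query, "gene_set"), inherits(annotation, "term_annotation"))
  uni <- annotation$universe$symbols
  q_in <- intersect(query$symbols, uni)
  if (length(q_in) == 0L)
    stop("no query gene maps into the annotation universe; nothing to test")
  coverage <- length(q_in) / length(query$symbols)
  n <- length(q_in)
  N <- length(uni)
  ids <- names(annotation$terms)
  rows <- lapply(ids, function(id) {
    t <- annotation$terms[[id]]
    K <- length(t$genes)
    k <- length(intersect(t$genes, q_in))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = t$description,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  res$q_value <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  attr(res, "coverage") <- coverage
  res
}
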