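#' Normalize raw gene symbol lines into a gene set
#'
#' Symbols are trimmed of surrounding whitespace, uppercased and
#' deduplicated. Blank lines and comment lines (starting with \code{#})
#' are dropped. No alias or identifier mapping is attempted: lists
#' exported from target-prediction databases are taken at face value.
#'
#' @param raw_lines character vector, one symbol per element.
#' @param name label for the set.
#' @return A \code{gene_set}: list with \code{name} and \code{symbols}
#'   (sorted character vector, unique, uppercase).
#' @export
normalize_symbols <- function(raw_lines, name = "set") {
  stopifnot(is.character(raw_lines) || length(raw_lines) == 0L)
  x <- trimws(as.character(raw_lines))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- toupper(x)
  structure(list(name = name, symbols = sort(unique(x))),
            class = "gene_set")
}

#' Read a plain-text gene list file
#'
#' One symbol per line, UTF-8; normalized via [normalize_symbols()].
#'
#' @param path file path.
#' @param name set label; defaults to the file name without extension.
#' @return a \code{gene_set}.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  normalize_symbols(readLines(path, warn = FALSE, encoding = "UTF-8"), name)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$symbols), " symbols\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Intersect two gene sets
#'
#' @param a,b \code{gene_set} objects (normalized).
#' @return a \code{gene_set} holding the shared symbols.
#' @export
intersect_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  normalize_symbols(intersect(a$symbols, b$symbols),
                    name = paste(a$name, b$name, sep = " & "))
}

#' Two-set Venn partition counts
#'
#' @param a,b \code{gene_set} objects.
#' @return list with \code{only_a}, \code{only_b}, \code{both}.
#' @export
venn_counts <- function(a, b) {
  both <- length(intersect(a$symbols, b$symbols))
  list(only_a = length(a$symbols) - both,
       only_b = length(b$symbols) - both,
       both = both)
}

#' Hypergeometric significance of a set overlap
#'
#' Upper-tail probability of observing at least \code{k} shared genes
#' when \code{n_b} genes are drawn without replacement from a universe of
#' \code{n_universe} genes of which \code{n_a} belong to the first set.
#' One-sided: only excess overlap is tested. The universe size must be
#' supplied by the caller; no genome-wide default is assumed.
#'
#' @param k observed overlap count.
#' @param n_a,n_b sizes of the two sets.
#' @param n_universe background universe size.
#' @return list with \code{k}, \code{n_a}, \code{n_b}, \code{n_universe},
#'   \code{p_value}.
#' @export
overlap_significance <- function(k, n_a, n_b, n_universe) {
  stopifnot(length(k) == 1L, length(n_a) == 1L, length(n_b) == 1L,
            length(n_universe) == 1L)
  if (k < 0 || n_a < 0 || n_b < 0 || n_universe < 1)
    stop("counts must be non-negative and the universe non-empty")
  if (k > min(n_a, n_b))
    stop("overlap k = ", k, " exceeds min(n_a, n_b) = ", min(n_a, n_b))
  if (n_a > n_universe || n_b > n_universe)
    stop("set size exceeds the universe size")
  if (n_a + n_b - k > n_universe)
    stop("sets of these sizes cannot overlap in only ", k,
         " genes within a universe of ", n_universe)
  p <- stats::phyper(k - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
  list(k = as.integer(k), n_a = as.integer(n_a), n_b = as.integer(n_b),
       n_universe = as.integer(n_universe), p_value = p)
}

#' Overlap summary of two gene lists against a universe
#'
#' Convenience wrapper producing one record with the Venn partition and
#' the hypergeometric overlap p-value, as written by the overlap stage.
#'
#' @param a,b \code{gene_set} objects.
#' @param n_universe background universe size.
#' @return one-row \code{data.frame} with columns \code{set_a},
#'   \code{set_b}, \code{only_a}, \code{only_b}, \code{both},
#'   \code{universe}, \code{p_value}.
#' @export
overlap_summary <- function(a, b, n_universe) {
  vc <- venn_counts(a, b)
  ot <- overlap_significance(vc$both, length(a$symbols), length(b$symbols),
                             n_universe)
  data.frame(set_a = a$name, set_b = b$name,
             only_a = vc$only_a, only_b = vc$only_b, both = vc$both,
             universe = as.integer(n_universe), p_value = ot$p_value,
             stringsAsFactors = FALSE)
}
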