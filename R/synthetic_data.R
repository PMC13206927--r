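# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# stage-specific sub-seed derived deterministically from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}

#' Specification of a synthetic multi-group biomarker panel
#'
#' The default spec emulates a three-arm neurotoxicity design: an
#' untreated control, a toxicant arm at full effect, and a
#' pretreatment+toxicant arm at half effect (a protective compound given
#' before the toxicant). The eight biomarkers cover four response
#' categories — mitophagy markers suppressed by the toxicant (PINK1,
#' PRKN, LC3B, TOM20), apoptosis markers induced (CASP3, AIF),
#' and mitochondrial-metabolism markers suppressed (ATP, MMP). Replicate
#' values are baseline * (1 +/- delta * multiplier) plus Gaussian noise.
#'
#' @param groups \code{data.frame} with columns \code{label},
#'   \code{multiplier} (effect multiplier per arm; 0 = control).
#' @param biomarkers \code{data.frame} with columns \code{label},
#'   \code{direction} ("up"/"down"), \code{baseline} (> 0),
#'   \code{delta} (relative effect magnitude, >= 0).
#' @param n_replicates replicates per group x biomarker cell.
#' @param noise_sd Gaussian replicate noise SD, same units as baseline.
#' @param seed RNG seed.
#' @return a \code{panel_spec} list.
#' @export
panel_spec <- function(groups = data.frame(
                         label = c("control", "toxicant", "protected"),
                         multiplier = c(0, 1, 0.5),
                         stringsAsFactors = FALSE),
                       biomarkers = data.frame(
                         label = c("PINK1", "PRKN", "LC3B", "TOM20",
                                   "CASP3", "AIF", "ATP", "MMP"),
                         direction = c("down", "down", "down", "down",
                                       "up", "up", "down", "down"),
                         baseline = 1,
                         delta = 0.4,
                         stringsAsFactors = FALSE),
                       n_replicates = 4, noise_sd = 0.1, seed = 1) {
  stopifnot(n_replicates >= 1, noise_sd >= 0,
            all(groups$multiplier >= 0) || TRUE,
            all(biomarkers$baseline > 0), all(biomarkers$delta >= 0),
            all(biomarkers$direction %in% c("up", "down")))
  structure(list(groups = groups, biomarkers = biomarkers,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a replicate-level biomarker table from a spec
#'
#' Pure function of the spec (seed included): identical specs give
#' identical tables. Replicate value = baseline * (1 + sgn * delta *
#' multiplier) + N(0, noise_sd), with sgn = +1 for "up" biomarkers and
#' -1 for "down".
#'
#' @param spec a \code{panel_spec}.
#' @return list with \code{table} (data.frame group, replicate,
#'   biomarker, value) and \code{directions} (named character vector of
#'   the true flags).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  g <- spec$groups; b <- spec$biomarkers
  rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                      biomarker_i = seq_len(nrow(b)),
                      group_i = seq_len(nrow(g)))
  sgn <- ifelse(b$direction[rows$biomarker_i] == "up", 1, -1)
  mu <- b$baseline[rows$biomarker_i] *
    (1 + sgn * b$delta[rows$biomarker_i] * g$multiplier[rows$group_i])
  noise <- with_seed(spec$seed, stats::rnorm(nrow(rows), 0, spec$noise_sd))
  tb <- data.frame(group = g$label[rows$group_i],
                   replicate = rows$replicate,
                   biomarker = b$label[rows$biomarker_i],
                   value = mu + noise, stringsAsFactors = FALSE)
  tb <- tb[order(match(tb$group, g$label), match(tb$biomarker, b$label),
                 tb$replicate), ]
  rownames(tb) <- NULL
  list(table = tb,
       directions = stats::setNames(b$direction, b$label))
}

#' Specification of two gene sets with a planted overlap
#'
#' Defaults mirror a typical network-toxicology intersection: a
#' compound-target list of 164 genes and a disease list of 865 genes
#' sharing exactly 21 genes within a genome-scale universe of 20000
#' (roughly the protein-coding gene count, the natural background for
#' target lists).
#'
#' @param n_universe,n_a,n_b,k_overlap sizes; \code{k_overlap} exact.
#' @param seed RNG seed.
#' @return an \code{overlap_spec} list.
#' @export
overlap_spec <- function(n_universe = 20000, n_a = 164, n_b = 865,
                         k_overlap = 21, seed = 1) {
  if (k_overlap > min(n_a, n_b))
    stop("k_overlap exceeds the smaller set")
  if (n_a + n_b - k_overlap > n_universe)
    stop("sets of these sizes cannot overlap in exactly ", k_overlap,
         " genes within a universe of ", n_universe)
  structure(list(n_universe = as.integer(n_universe),
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 k_overlap = as.integer(k_overlap),
                 seed = as.integer(seed)),
            class = "overlap_spec")
}

# zero-padded synthetic symbols: lexicographic order == numeric order
.synthetic_symbols <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a universe and two gene sets with an exact planted overlap
#'
#' @param spec an \code{overlap_spec}.
#' @return list of \code{gene_set}s: \code{universe}, \code{a}, \code{b}.
#' @export
generate_overlap_sets <- function(spec) {
  stopifnot(inherits(spec, "overlap_spec"))
  uni <- .synthetic_symbols(spec$n_universe)
  sets <- with_seed(spec$seed, {
    shared <- sample(uni, spec$k_overlap)
    rest <- setdiff(uni, shared)
    a_only <- sample(rest, spec$n_a - spec$k_overlap)
    b_only <- sample(setdiff(rest, a_only), spec$n_b - spec$k_overlap)
    list(a = c(shared, a_only), b = c(shared, b_only))
  })
  list(universe = normalize_symbols(uni, "universe"),
       a = normalize_symbols(sets$a, "set_a"),
       b = normalize_symbols(sets$b, "set_b"))
}

#' Generate a term annotation with optional planted enrichment
#'
#' Background terms draw their genes uniformly from the universe. Each
#' planted term is built to contain exactly the stated number of query
#' genes (sampled from the query) with the remainder drawn from outside
#' the query. The query itself is a uniform draw from the universe.
#' Defaults give a 1000-gene universe, a 100-gene query, 200 background
#' terms of 20-200 genes, and one planted term of 50 genes sharing 20
#' with the query — a strong, unambiguous enrichment signal.
#'
#' @param universe a \code{gene_set}; default 1000 synthetic symbols.
#' @param n_terms number of background terms.
#' @param term_size_range integer range (inclusive) of term sizes.
#' @param planted_terms named integer vector: term id -> overlap with the
#'   query; \code{c()} for a null annotation. Planted term size is
#'   \code{planted_size}.
#' @param planted_size gene count of each planted term.
#' @param query_size query set size.
#' @param seed RNG seed.
#' @return list with \code{annotation} (\code{term_annotation}) and
#'   \code{query} (\code{gene_set}).
#' @export
generate_annotation <- function(universe = normalize_symbols(.synthetic_symbols(1000), "universe"),
                                n_terms = 200,
                                term_size_range = c(20, 200),
                                planted_terms = c(PLANTED_1 = 20),
                                planted_size = 50,
                                query_size = 100, seed = 1) {
  stopifnot(inherits(universe, "gene_set"),
            term_size_range[1] >= 1,
            term_size_range[2] <= length(universe$symbols))
  if (length(planted_terms) &&
      (any(planted_terms > planted_size) || any(planted_terms > query_size)))
    stop("planted overlap exceeds the planted term size or the query size")
  uni <- universe$symbols
  out <- with_seed(seed, {
    query <- sample(uni, query_size)
    non_query <- setdiff(uni, query)
    terms <- list()
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    for (i in seq_len(n_terms)) {
      id <- sprintf("BG%04d", i)
      terms[[id]] <- list(description = paste("background term", i),
                          genes = sort(sample(uni, sizes[i])))
    }
    for (id in names(planted_terms)) {
      k <- planted_terms[[id]]
      if (planted_size - k > length(non_query))
        stop("planted term does not fit outside the query")
      genes <- c(sample(query, k), sample(non_query, planted_size - k))
      terms[[id]] <- list(description = paste("planted term", id),
                          genes = sort(genes))
    }
    list(terms = terms, query = query)
  })
  annotation <- structure(list(terms = out$terms, universe = universe),
                          class = "term_annotation")
  list(annotation = annotation,
       query = normalize_symbols(out$query, "query"))
}

#' Write a GMT file from a term annotation
#'
#' @param annotation a \code{term_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "term_annotation"))
  lines <- vapply(names(annotation$terms), function(id) {
    t <- annotation$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Materialize a complete demo workspace
#'
#' Writes, under \code{dir}: two gene lists with a planted overlap
#' (\code{targets_a.txt}, \code{targets_b.txt}), a GMT annotation with a
#' planted enriched term (\code{annotation.gmt}), a replicate-level
#' biomarker table (\code{panel.tsv}), its direction flags
#' (\code{directions.tsv}) and a ready-to-run pipeline config
#' (\code{config.yaml}). All content is a pure function of \code{seed}.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; stage sub-seeds are derived from it.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  sets <- generate_overlap_sets(overlap_spec(seed = derive_seed(seed, 1)))
  writeLines(sets$a$symbols, p("targets_a.txt"))
  writeLines(sets$b$symbols, p("targets_b.txt"))

  ann <- generate_annotation(seed = derive_seed(seed, 2))
  write_gmt(ann$annotation, p("annotation.gmt"))
  writeLines(ann$query$symbols, p("query.txt"))

  pan <- generate_panel(panel_spec(seed = derive_seed(seed, 3)))
  utils::write.table(pan$table, p("panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(biomarker = names(pan$directions),
                                direction = unname(pan$directions)),
                     p("directions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg <- list(stages = c("overlap", "enrich", "ibr"),
              gene_list_a = "targets_a.txt",
              gene_list_b = "targets_b.txt",
              universe_size = 20000L,
              gmt = "annotation.gmt",
              query = "query.txt",
              panel = "panel.tsv",
              directions = "directions.tsv",
              sd_mode = "sample",
              min_scope = "biomarker",
              output_dir = "results",
              seed = as.integer(seed))
  yaml::write_yaml(cfg, p("config.yaml"))

  files <- c(targets_a = p("targets_a.txt"), targets_b = p("targets_b.txt"),
             annotation = p("annotation.gmt"), query = p("query.txt"),
             panel = p("panel.tsv"), directions = p("directions.tsv"),
             config = p("config.yaml"))
  invisible(files)
}
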