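#' Load and validate a pipeline configuration
#'
#' YAML config with the stage list and input paths. Relative paths are
#' resolved against the config file's directory. Validation checks that
#' every path referenced by a requested stage exists and that enumerated
#' options take declared values, before any stage runs.
#'
#' Recognized keys: \code{stages} (subset of overlap, enrich, ibr),
#' \code{gene_list_a}, \code{gene_list_b}, \code{universe_size},
#' \code{gmt}, \code{query}, \code{panel}, \code{directions},
#' \code{sd_mode}, \code{min_scope}, \code{output_dir}, \code{seed}.
#'
#' @param path YAML config path.
#' @return validated config list (class \code{pipeline_config}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)

  cfg$stages <- as.character(cfg$stages %||% c("overlap", "enrich", "ibr"))
  bad <- setdiff(cfg$stages, c("overlap", "enrich", "ibr"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$sd_mode <- cfg$sd_mode %||% "sample"
  cfg$min_scope <- cfg$min_scope %||% "biomarker"
  if (!cfg$sd_mode %in% c("sample", "population"))
    stop("sd_mode must be 'sample' or 'population'")
  if (!cfg$min_scope %in% c("biomarker", "global"))
    stop("min_scope must be 'biomarker' or 'global'")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- resolve(cfg$output_dir %||% "results")

  need <- list(overlap = c("gene_list_a", "gene_list_b"),
               enrich = c("gmt"),
               ibr = c("panel", "directions"))
  for (st in cfg$stages) for (key in need[[st]]) {
    if (is.null(cfg[[key]]))
      stop("stage '", st, "' requires config key '", key, "'")
    cfg[[key]] <- resolve(cfg[[key]])
    if (!file.exists(cfg[[key]]))
      stop("stage '", st, "': file for '", key, "' not found: ", cfg[[key]])
  }
  if ("overlap" %in% cfg$stages && is.null(cfg$universe_size))
    stop("stage 'overlap' requires an explicit universe_size")
  if (!is.null(cfg$query)) {
    cfg$query <- resolve(cfg$query)
    if (!file.exists(cfg$query)) stop("query file not found: ", cfg$query)
  }
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message("[", stage, "] ", ...)
}

#' Run the analysis pipeline described by a config
#'
#' Executes the requested stages in the fixed order overlap, enrich, ibr.
#' The enrichment query is, in order of preference: the config's
#' \code{query} list, else the intersection computed by the overlap stage
#' (the usual network-toxicology flow: enrich the shared targets).
#' Outputs land in \code{output_dir}: \code{overlap.tsv},
#' \code{enrichment.tsv}, \code{ibr_scores.tsv}, \code{ibr_index.json},
#' \code{radar.svg}, plus \code{manifest.json} listing every output with
#' an md5 checksum. Re-running an identical config over identical inputs
#' reproduces identical checksums.
#'
#' @param config a \code{pipeline_config} (from [load_config()]) or a
#'   path to one.
#' @param quiet suppress stage log messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  outputs <- character(0)
  overlap_set <- NULL

  if ("overlap" %in% config$stages) {
    .stage_log("overlap", "intersecting gene lists", quiet = quiet)
    a <- read_gene_list(config$gene_list_a)
    b <- read_gene_list(config$gene_list_b)
    summ <- overlap_summary(a, b, config$universe_size)
    overlap_set <- intersect_sets(a, b)
    outputs <- c(outputs, .write_tsv(summ, out("overlap.tsv")))
    jsonlite::write_json(as.list(summ), out("overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(overlap_set$symbols, out("overlap_genes.txt"))
    outputs <- c(outputs, out("overlap.json"), out("overlap_genes.txt"))
    .stage_log("overlap", "both = ", summ$both, ", p = ",
               signif(summ$p_value, 3), quiet = quiet)
  }

  if ("enrich" %in% config$stages) {
    .stage_log("enrich", "over-representation analysis", quiet = quiet)
    ann <- load_gmt(config$gmt)
    query <- if (!is.null(config$query)) read_gene_list(config$query)
             else if (!is.null(overlap_set)) overlap_set
             else stop("stage 'enrich': no query list and no overlap stage output")
    res <- run_ora(query, ann)
    outputs <- c(outputs, .write_tsv(res, out("enrichment.tsv")))
    .stage_log("enrich", nrow(res), " terms, min q = ",
               signif(min(res$q_value), 3), quiet = quiet)
  }

  if ("ibr" %in% config$stages) {
    .stage_log("ibr", "integrated biomarker response", quiet = quiet)
    tb <- utils::read.delim(config$panel, stringsAsFactors = FALSE)
    dirs <- utils::read.delim(config$directions, stringsAsFactors = FALSE)
    panel <- build_panel(tb, dirs)
    res <- compute_ibr(panel, sd_mode = config$sd_mode,
                       min_scope = config$min_scope)
    long <- data.frame(
      group = rep(rownames(res$S), ncol(res$S)),
      biomarker = rep(colnames(res$S), each = nrow(res$S)),
      Y = as.vector(res$Y), Z = as.vector(res$Z), S = as.vector(res$S),
      stringsAsFactors = FALSE)
    outputs <- c(outputs, .write_tsv(long, out("ibr_scores.tsv")))
    jsonlite::write_json(as.list(res$ibr_index), out("ibr_index.json"),
                         auto_unbox = TRUE, digits = NA)
    write_radar_svg(res, out("radar.svg"))
    outputs <- c(outputs, out("ibr_index.json"), out("radar.svg"))
    .stage_log("ibr", paste(names(res$ibr_index),
                            signif(res$ibr_index, 4),
                            sep = " = ", collapse = ", "), quiet = quiet)
  }

  manifest <- list(
    package = "ibrtox",
    version = as.character(utils::packageVersion("ibrtox")),
    stages = config$stages,
    seed = config$seed,
    inputs = Filter(Negate(is.null),
                    list(gene_list_a = config$gene_list_a,
                         gene_list_b = config$gene_list_b,
                         gmt = config$gmt, query = config$query,
                         panel = config$panel,
                         directions = config$directions)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
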