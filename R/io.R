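## Readers and writers for the interchange formats: probe map TSV, log-ratio
## matrix TSV, expression matrix TSV, gene annotation BED-like TSV, network
## edge-list TSV (SIF accepted), clinical TSV, gene-set / driver / score TSVs,
## report JSON. All writers emit a '#'-prefixed provenance header (producing
## stage + config hash) that the readers skip. Genomic intervals are 0-based
## half-open throughout.

.INSS_STAGES <- c("1", "2", "3", "4", "4S")

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  ## small rolling hash; provenance marker only, not cryptographic
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stage_tsv <- function(df, path, stage, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else config_hash(config)
  writeLines(sprintf("# dgscore stage=%s config=%s intervals=0-based-half-open",
                     stage, hash), con)
  ## doubles at 17 significant digits so text round trips are bit-exact
  dbl <- vapply(df, is.double, logical(1))
  df[dbl] <- lapply(df[dbl], function(x) sprintf("%.17g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a probe-level log-ratio matrix with its probe map
#'
#' @param path TSV with header `probe_id` then sample ids; one row per probe.
#' @param probe_map_path companion TSV with columns `probe_id`, `chrom`,
#'   `pos`.
#' @param clinical optional clinical table; sample columns are validated
#'   against it and a missing sample is an error naming it.
#' @return List with `probe_map` (sorted by chrom, pos) and `log_ratios`
#'   (probe x sample matrix, rows in probe-map order).
#' @export
read_probe_matrix <- function(path, probe_map_path, clinical = NULL) {
  pm <- read_stage_tsv(probe_map_path)
  names(pm)[names(pm) == "probe_id"] <- "probe"
  if (anyDuplicated(pm$probe)) {
    dup <- pm$probe[duplicated(pm$probe)][1]
    stop("parse error: duplicate probe id '", dup, "' in ", probe_map_path,
         call. = FALSE)
  }
  pm <- pm[order(pm$chrom, pm$pos), ]
  mat_df <- read_stage_tsv(path)
  names(mat_df)[1] <- "probe"
  if (anyDuplicated(mat_df$probe)) {
    stop("parse error: duplicate probe id in ", path, call. = FALSE)
  }
  miss <- setdiff(pm$probe, mat_df$probe)
  if (length(miss)) {
    stop("parse error: probes missing from matrix: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(mat_df[-1], is.numeric, logical(1)))[1]
    stop("parse error: non-numeric cells in sample column '",
         names(mat_df)[-1][bad], "'", call. = FALSE)
  }
  rownames(m) <- mat_df$probe
  m <- m[pm$probe, , drop = FALSE]
  if (!is.null(clinical)) {
    miss <- setdiff(clinical$patient, colnames(m))
    if (length(miss)) {
      stop("parse error: sample(s) in clinical table but not in matrix: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  list(probe_map = pm[, c("probe", "chrom", "pos")], log_ratios = m)
}

#' Read a gene x sample FPKM expression matrix
#' @param path TSV: header `gene_id` then sample ids.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  d <- read_stage_tsv(path)
  if (anyDuplicated(d[[1]])) stop("parse error: duplicate gene ids", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (!is.numeric(m)) stop("parse error: non-numeric expression cells", call. = FALSE)
  m
}

#' Read an undirected interaction network from an edge list
#'
#' Accepts a 2-column TSV edge list or a SIF file (`a type b`, interaction
#' type ignored). Self-loops are dropped and duplicate edges (in either
#' orientation) are merged, each with a warning count.
#'
#' @param path edge-list path.
#' @return An undirected simple igraph network.
#' @export
read_network <- function(path) {
  d <- read_stage_tsv(path, header = FALSE)
  if (ncol(d) >= 3 && !all(is.na(d[[3]]))) d <- d[, c(1, 3)] # SIF: a type b
  else d <- d[, 1:2]
  names(d) <- c("a", "b")
  d[] <- lapply(d, as.character)
  loops <- d$a == d$b
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    d <- d[!loops, ]
  }
  key <- paste(pmin(d$a, d$b), pmax(d$a, d$b))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) merged")
    d <- d[!duplicated(key), ]
  }
  igraph::graph_from_data_frame(d, directed = FALSE)
}

#' Read the clinical table
#'
#' @param path TSV with columns `patient`, `os_days`, `os_event`, `age_days`,
#'   `stage` (INSS: 1, 2, 3, 4, 4S), `mycn_amp`, `high_risk`.
#' @return Validated data frame.
#' @export
read_clinical <- function(path) {
  d <- read_stage_tsv(path, colClasses = c(stage = "character"))
  need <- c("patient", "os_days", "os_event", "age_days", "stage",
            "mycn_amp", "high_risk")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("parse error: missing clinical column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(d$stage), .INSS_STAGES)
  if (length(bad)) stop("parse error: unknown INSS stage label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(d$os_days <= 0)) stop("parse error: os_days must be > 0", call. = FALSE)
  d
}

#' Read a BED-like gene annotation table
#' @param path TSV with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open).
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path) {
  d <- read_stage_tsv(path, header = FALSE)
  names(d)[1:4] <- c("chrom", "start", "end", "gene")
  if (any(d$end <= d$start)) stop("parse error: end <= start", call. = FALSE)
  d[, c("gene", "chrom", "start", "end")]
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits `probe_map.tsv`, `log_ratios.tsv`, `expression.tsv`,
#' `gene_annotation.bed`, `network.tsv`, `clinical.tsv` and `truth.json`
#' under `dir`.
#'
#' @param cohort a [generate_cohort()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  pm <- cohort$probe_map
  names(pm)[1] <- "probe_id"
  write_stage_tsv(pm, file.path(dir, "probe_map.tsv"), "simulate", cfg)
  lr <- data.frame(probe_id = rownames(cohort$log_ratios),
                   cohort$log_ratios, check.names = FALSE)
  write_stage_tsv(lr, file.path(dir, "log_ratios.tsv"), "simulate", cfg)
  ex <- data.frame(gene_id = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE)
  write_stage_tsv(ex, file.path(dir, "expression.tsv"), "simulate", cfg)
  bed <- cohort$gene_annotation[, c("chrom", "start", "end", "gene")]
  con <- file(file.path(dir, "gene_annotation.bed"), "w")
  writeLines(sprintf("# dgscore stage=simulate config=%s intervals=0-based-half-open",
                     config_hash(cfg)), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  el <- igraph::as_edgelist(cohort$network)
  utils::write.table(el, file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_stage_tsv(cohort$clinical, file.path(dir, "clinical.tsv"),
                  "simulate", cfg)
  truth <- cohort$truth
  truth$region_carrier_direction <- lapply(truth$region_carrier_direction,
                                           as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write recurrent regions as BED (carrier count in the score column)
#' @param regions region data frame from [detect_recurrent_regions()].
#' @param path output path.
#' @param config optional config for the provenance header.
#' @export
write_regions_bed <- function(regions, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else config_hash(config)
  writeLines(sprintf("# dgscore stage=recur config=%s intervals=0-based-half-open",
                     hash), con)
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    paste0("region_", regions$region_id),
                    regions$n_carriers, ".")
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
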