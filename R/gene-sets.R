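#' Preprocess an FPKM expression matrix
#'
#' Log-transforms (`log2(FPKM + 1)`), standardises within each patient (column
#' mean 0, variance 1 over genes) and ranks every gene's standardised values
#' across patients (average ranks for ties). The cross-patient ranks are what
#' patient-specific extreme-expression gene sets are built from.
#'
#' @param values gene x patient nonnegative FPKM matrix with dimnames.
#' @return Object of class `expression_matrix`: list with `values`, `log2`,
#'   `scaled` (within-patient standardised) and `ranks` (per-gene cross-patient
#'   ranks) matrices, all gene x patient.
#' @export
preprocess_expression <- function(values) {
  stopifnot(is.matrix(values), nrow(values) >= 2,
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("input error: negative FPKM values", call. = FALSE)
  l2 <- log2(values + 1)
  sds <- apply(l2, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate input: patient(s) with zero expression variance: ",
         paste(colnames(values)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scaled <- scale(l2)
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  ranks <- t(apply(scaled, 1, rank, ties.method = "average"))
  dimnames(ranks) <- dimnames(values)
  structure(list(values = values, log2 = l2, scaled = scaled, ranks = ranks),
            class = "expression_matrix")
}

#' Assign genes to recurrent regions by genomic overlap
#'
#' A gene belongs to a region iff their half-open intervals overlap by at
#' least 1 bp on the same chromosome; a gene may belong to several regions.
#'
#' @param regions data frame with `region_id`, `chrom`, `start`, `end`.
#' @param gene_annotation data frame with `gene`, `chrom`, `start`, `end`.
#' @return Data frame with columns `region_id`, `gene`.
#' @export
annotate_regions <- function(regions, gene_annotation) {
  if (!nrow(regions)) {
    return(data.frame(region_id = integer(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- gene_annotation$chrom == regions$chrom[i] &
      gene_annotation$start < regions$end[i] &
      gene_annotation$end > regions$start[i]
    if (!any(hit)) return(NULL)
    data.frame(region_id = regions$region_id[i],
               gene = gene_annotation$gene[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(region_id = integer(), gene = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sided Welch concordance test for a copy-number-altered gene
#'
#' Tests whether carriers of a gain over-express the gene relative to
#' copy-number-neutral patients (alternative `greater`), or under-express it
#' for a loss (alternative `less`), on the within-patient standardised scale.
#' A gene is kept at `p < alpha` (no multiple-testing correction: the pipeline
#' stacks several filters and prioritises sensitivity at this step).
#'
#' @param gene gene id.
#' @param expr an [preprocess_expression()] object.
#' @param carriers patient ids with the alteration.
#' @param neutral patient ids with normal copy number at the gene.
#' @param direction `"gain"` or `"loss"`.
#' @param alpha significance level (default 0.05).
#' @return One-row data frame: `gene`, `direction`, `n_carriers`, `n_neutral`,
#'   `t_statistic`, `df`, `p_one_sided`, `kept`; or the same row with `NA`
#'   statistics and `kept = NA` when a group has fewer than two patients.
#' @export
concordance_filter <- function(gene, expr, carriers, neutral, direction,
                               alpha = 0.05) {
  direction <- match.arg(direction, c("gain", "loss"))
  row <- data.frame(gene = gene, direction = direction,
                    n_carriers = length(carriers), n_neutral = length(neutral),
                    t_statistic = NA_real_, df = NA_real_,
                    p_one_sided = NA_real_, kept = NA,
                    stringsAsFactors = FALSE)
  if (length(carriers) < 2 || length(neutral) < 2) return(row)
  x <- expr$scaled[gene, carriers]
  y <- expr$scaled[gene, neutral]
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(row)
  alt <- if (direction == "gain") "greater" else "less"
  tt <- stats::t.test(x, y, alternative = alt, var.equal = FALSE)
  row$t_statistic <- unname(tt$statistic)
  row$df <- unname(tt$parameter)
  row$p_one_sided <- tt$p.value
  row$kept <- tt$p.value < alpha
  row
}

## Per-gene alteration states across patients, from filtered CNAs:
## data frame (gene, patient, state) for every annotated gene covered by a
## patient's CNA (>= 1 bp overlap).
gene_alteration_states <- function(genes, gene_annotation, cnas) {
  ann <- gene_annotation[match(genes, gene_annotation$gene), ]
  if (is.null(cnas) || !nrow(cnas)) {
    return(data.frame(gene = character(), patient = character(),
                      state = character(), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(cnas)), function(i) {
    hit <- ann$chrom == cnas$chrom[i] &
      ann$start < cnas$end[i] & ann$end > cnas$start[i]
    if (!any(hit)) return(NULL)
    data.frame(gene = ann$gene[hit], patient = cnas$patient[i],
               state = cnas$state[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(gene = character(), patient = character(),
                                      state = character(), stringsAsFactors = FALSE))
  unique(out)
}

#' Build the functional gene set (FGS)
#'
#' Annotates all genes on recurrent regions and keeps those whose expression
#' is concordant with their alteration: carriers of a gain must over-express
#' the gene (and carriers of a loss under-express it) relative to
#' copy-number-neutral patients, by one-sided Welch test at `alpha`. A gene
#' altered in both directions is tested per direction and kept if any
#' direction is concordant.
#'
#' @param regions output of [detect_recurrent_regions()] (list with `regions`
#'   and `carriers`).
#' @param gene_annotation gene coordinate table.
#' @param expr an [preprocess_expression()] object.
#' @param cnas pooled filtered CNAs of the cohort.
#' @param alpha concordance significance level.
#' @return Object of class `fgs`: list with `genes` (kept gene ids), `tests`
#'   (all concordance rows), `annotation` (region_id/gene map), `alterations`
#'   (gene/patient/state rows for annotated genes) and `regions` (the input
#'   region list).
#' @export
build_fgs <- function(regions, gene_annotation, expr, cnas, alpha = 0.05) {
  ann <- annotate_regions(regions$regions, gene_annotation)
  genes <- unique(ann$gene)
  genes <- genes[genes %in% rownames(expr$scaled)]
  alt <- gene_alteration_states(genes, gene_annotation, cnas)
  all_pat <- colnames(expr$scaled)
  tests <- list()
  for (g in genes) {
    rows <- alt[alt$gene == g, ]
    neutral <- setdiff(all_pat, rows$patient)
    for (dir in intersect(c("gain", "loss"), unique(rows$state))) {
      car <- rows$patient[rows$state == dir]
      car <- intersect(car, all_pat)
      tests[[length(tests) + 1L]] <-
        concordance_filter(g, expr, car, neutral, dir, alpha)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(gene = character(), direction = character(),
               n_carriers = integer(), n_neutral = integer(),
               t_statistic = numeric(), df = numeric(),
               p_one_sided = numeric(), kept = logical(),
               stringsAsFactors = FALSE)
  kept <- unique(tests$gene[!is.na(tests$kept) & tests$kept])
  structure(list(genes = kept, tests = tests, annotation = ann,
                 alterations = alt, regions = regions),
            class = "fgs")
}

#' Reduce the FGS to genes from direction-pure regions
#'
#' For common-driver calling the candidate pool is restricted by excluding
#' every recurrent region whose carriers mix gains and losses; only FGS genes
#' all of whose containing regions are direction-pure remain, each tagged with
#' its region direction.
#'
#' @param fgs output of [build_fgs()].
#' @return Data frame with columns `gene`, `direction`.
#' @export
build_common_fgs <- function(fgs) {
  carr <- fgs$regions$carriers
  if (!length(fgs$genes)) {
    return(data.frame(gene = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  purity <- vapply(split(carr$direction, carr$region_id),
                   function(d) length(unique(d)) == 1L, logical(1))
  region_dir <- vapply(split(carr$direction, carr$region_id),
                       function(d) d[1], character(1))
  res <- lapply(fgs$genes, function(g) {
    regs <- as.character(fgs$annotation$region_id[fgs$annotation$gene == g])
    if (!length(regs) || !all(purity[regs])) return(NULL)
    data.frame(gene = g, direction = region_dir[regs[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene = character(), direction = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Patient-specific extreme-expression gene set (AGS)
#'
#' The patient's altered gene set is the `top_n` genes for which this patient
#' holds the highest cross-patient ranks (up-set) plus the `top_n` with the
#' lowest ranks (down-set). Rank ties are broken by the magnitude of the
#' patient's standardised expression, then lexicographically by gene id, so
#' the set is deterministic.
#'
#' @param expr an [preprocess_expression()] object.
#' @param patient patient id (a column of the expression matrix).
#' @param top_n genes per tail (default 100, giving a 200-gene AGS).
#' @return Data frame with columns `gene`, `direction` (`up`/`down`),
#'   `patient`.
#' @export
build_patient_ags <- function(expr, patient, top_n = 100) {
  genes <- rownames(expr$ranks)
  if (length(genes) < 2 * top_n) {
    stop("invalid-config: need at least 2 * top_n genes", call. = FALSE)
  }
  if (!patient %in% colnames(expr$ranks)) {
    stop("input error: unknown patient ", patient, call. = FALSE)
  }
  r <- expr$ranks[, patient]
  s <- expr$scaled[, patient]
  up <- genes[order(-r, -s, genes)][seq_len(top_n)]
  down <- genes[order(r, s, genes)][seq_len(top_n)]
  data.frame(gene = c(up, down),
             direction = rep(c("up", "down"), each = top_n),
             patient = patient, stringsAsFactors = FALSE)
}

#' Common altered gene set across patients, optionally extended by a
#' literature list
#'
#' Pools all patient-specific AGS and keeps genes recurrent in at least
#' `min_recurrence` patients; a supplied literature gene list (e.g. known
#' disease genes) extends this common set, restricted to genes present in the
#' analysis universe.
#'
#' @param patient_ags list (or rbind-able data frames) of [build_patient_ags()]
#'   outputs, one per patient.
#' @param min_recurrence minimum number of patients an expression-derived gene
#'   must appear in (default 5).
#' @param literature_genes character vector of literature gene ids (may be
#'   empty; a warning notes the expression-only fallback).
#' @param universe gene ids admissible in the analysis (typically the union of
#'   network nodes and expression genes); literature genes outside it are
#'   dropped with a message.
#' @return Data frame with columns `gene`, `provenance`
#'   (`expression`/`literature`/`both`), `n_patients` (AGS recurrence count,
#'   0 for literature-only genes).
#' @export
build_common_ags <- function(patient_ags, min_recurrence = 5,
                             literature_genes = character(),
                             universe = NULL) {
  ags_all <- if (is.data.frame(patient_ags)) patient_ags else
    do.call(rbind, patient_ags)
  per_patient <- unique(ags_all[, c("gene", "patient")])
  counts <- table(per_patient$gene)
  expr_genes <- names(counts)[counts >= min_recurrence]
  if (!length(literature_genes)) {
    warning("empty literature gene list; common AGS is expression-derived only")
  }
  lit <- unique(literature_genes)
  if (!is.null(universe)) {
    dropped <- setdiff(lit, universe)
    if (length(dropped)) {
      message(length(dropped), " literature gene(s) absent from the universe, dropped")
    }
    lit <- intersect(lit, universe)
  }
  genes <- union(expr_genes, lit)
  if (!length(genes)) {
    return(data.frame(gene = character(), provenance = character(),
                      n_patients = integer(), stringsAsFactors = FALSE))
  }
  prov <- ifelse(genes %in% expr_genes & genes %in% lit, "both",
                 ifelse(genes %in% lit, "literature", "expression"))
  data.frame(gene = genes, provenance = prov,
             n_patients = as.integer(ifelse(genes %in% names(counts),
                                            counts[genes], 0L)),
             stringsAsFactors = FALSE)
}
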