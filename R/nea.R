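#' Count direct network links between a candidate gene and an AGS
#'
#' Number of AGS members adjacent to the candidate in the interaction
#' network; the candidate itself is excluded from the AGS before counting, so
#' a gene can never be enriched by its own membership.
#'
#' @param candidate gene id (must be a network node).
#' @param ags character vector of AGS gene ids.
#' @param network an undirected [igraph][igraph::igraph-package] network.
#' @return Integer link count `d_AF`.
#' @export
count_links <- function(candidate, ags, network) {
  if (!candidate %in% igraph::V(network)$name) {
    stop("undetermined: candidate not in network: ", candidate, call. = FALSE)
  }
  nb <- igraph::neighbors(network, candidate)$name
  length(intersect(nb, setdiff(unique(ags), candidate)))
}

#' Network enrichment z-score for one candidate gene
#'
#' Scores the over-representation of direct links between a candidate
#' (copy-number-altered) gene and an altered gene set as
#' `z = (d_AF - mu_AF) / sigma_AF`, where `d_AF` is the observed link count
#' and `mu_AF`, `sigma_AF` are its null mean and standard deviation.
#'
#' Null models:
#' \describe{
#'   \item{`hypergeometric` (default)}{the AGS is a uniform draw of `a` genes
#'     from the `N - 1` non-candidate nodes, so
#'     `d_AF ~ Hypergeometric(N - 1, k, a)` with `mu = a k / (N - 1)` and
#'     `sigma^2 = a (k / (N - 1)) (1 - k / (N - 1)) (N - 1 - a) / (N - 2)`.
#'     Deterministic and exactly enumerable, but not degree-corrected for the
#'     AGS members.}
#'   \item{`degree_product`}{configuration-model expectation
#'     `mu = k * D_AGS / (2 m)` with `D_AGS` the AGS degree sum, and a Poisson
#'     spread `sigma = sqrt(mu)`; degree-aware and cheap.}
#'   \item{`edge_permutation`}{empirical `mu`, `sigma` of `d_AF` over
#'     `n_permutations` degree-preserving rewirings of the whole network.}
#' }
#'
#' @param candidate gene id.
#' @param ags character vector of AGS gene ids.
#' @param network undirected igraph network.
#' @param null_kind one of `"hypergeometric"`, `"degree_product"`,
#'   `"edge_permutation"`.
#' @param n_permutations rewirings for the permutation null.
#' @param seed integer seed for the permutation null.
#' @return One-row data frame: `candidate`, `ags_size`, `k` (candidate
#'   degree), `d_af`, `mu_af`, `sigma_af`, `z`, `null_kind`. `z` is `NA` (with
#'   a warning) when `sigma_af` is 0, e.g. for an isolated candidate.
#' @export
nea_zscore <- function(candidate, ags, network,
                       null_kind = c("hypergeometric", "degree_product",
                                     "edge_permutation"),
                       n_permutations = 1000, seed = 1L) {
  null_kind <- match.arg(null_kind)
  nodes <- igraph::V(network)$name
  N <- length(nodes)
  ags_eff <- intersect(setdiff(unique(ags), candidate), nodes)
  a <- length(ags_eff)
  if (a == 0) stop("invalid: AGS empty (after network restriction)", call. = FALSE)
  if (a >= N - 1) stop("invalid: AGS spans the whole network", call. = FALSE)
  k <- igraph::degree(network, candidate)
  d <- count_links(candidate, ags_eff, network)

  if (null_kind == "hypergeometric") {
    p <- k / (N - 1)
    mu <- a * p
    sigma <- sqrt(a * p * (1 - p) * (N - 1 - a) / (N - 2))
  } else if (null_kind == "degree_product") {
    m <- igraph::ecount(network)
    mu <- k * sum(igraph::degree(network, ags_eff)) / (2 * m)
    sigma <- sqrt(mu)
  } else {
    set.seed(seed)
    m <- igraph::ecount(network)
    d_perm <- vapply(seq_len(n_permutations), function(b) {
      g2 <- igraph::rewire(network, igraph::keeping_degseq(niter = 10 * m))
      count_links(candidate, ags_eff, g2)
    }, numeric(1))
    mu <- mean(d_perm)
    sigma <- stats::sd(d_perm)
  }
  z <- if (sigma > 0) (d - mu) / sigma else NA_real_
  if (is.na(z)) {
    warning("sigma_AF = 0 for candidate ", candidate, "; z undefined, gene skipped")
  }
  data.frame(candidate = candidate, ags_size = a, k = as.integer(k),
             d_af = as.integer(d), mu_af = mu, sigma_af = sigma, z = z,
             null_kind = null_kind, stringsAsFactors = FALSE)
}

## Score a vector of candidates against one AGS; candidates missing from the
## network are skipped with a message.
nea_score_set <- function(candidates, ags, network, null_kind, seed = 1L,
                          n_permutations = 1000) {
  nodes <- igraph::V(network)$name
  missing <- setdiff(candidates, nodes)
  if (length(missing)) {
    message(length(missing), " candidate(s) absent from network, skipped")
  }
  candidates <- intersect(candidates, nodes)
  n_degenerate <- 0L
  res <- lapply(seq_along(candidates), function(i) {
    tryCatch(
      nea_zscore(candidates[i], ags, network, null_kind = null_kind,
                 n_permutations = n_permutations,
                 seed = seed + 7919L * i),  # deterministic per-gene substream
      error = function(e) {
        if (!grepl("spans", conditionMessage(e))) stop(e)
        n_degenerate <<- n_degenerate + 1L
        NULL
      })
  })
  if (n_degenerate > 0) {
    warning("AGS spans the whole network for ", n_degenerate,
            " candidate(s); enrichment undefined, gene(s) skipped")
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(candidate = character(), ags_size = integer(),
                      k = integer(), d_af = integer(), mu_af = numeric(),
                      sigma_af = numeric(), z = numeric(),
                      null_kind = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Call common driver genes
#'
#' Scores every gene of the direction-pure FGS against the cohort-level common
#' AGS and calls putative drivers at `z > z_threshold` (default 2).
#'
#' @param fgs_common data frame from [build_common_fgs()] (or a character
#'   vector of gene ids).
#' @param ags_common data frame from [build_common_ags()] (or a character
#'   vector).
#' @param network undirected igraph network.
#' @param z_threshold driver-calling threshold on z (strict inequality).
#' @param null_kind,seed,n_permutations passed to [nea_zscore()].
#' @return Data frame of calls: `gene`, `scope` (`"common"`), NEA columns.
#'   All scored candidates are kept in the `"scores"` attribute.
#' @export
call_common_drivers <- function(fgs_common, ags_common, network,
                                z_threshold = 2,
                                null_kind = "hypergeometric", seed = 1L,
                                n_permutations = 1000) {
  cand <- if (is.data.frame(fgs_common)) fgs_common$gene else fgs_common
  ags <- if (is.data.frame(ags_common)) ags_common$gene else ags_common
  empty <- data.frame(gene = character(), scope = character(),
                      ags_size = integer(), k = integer(), d_af = integer(),
                      mu_af = numeric(), sigma_af = numeric(), z = numeric(),
                      null_kind = character(), stringsAsFactors = FALSE)
  if (!length(cand) || !length(ags)) return(empty)
  sc <- nea_score_set(unique(cand), ags, network, null_kind, seed,
                      n_permutations)
  calls <- sc[!is.na(sc$z) & sc$z > z_threshold, , drop = FALSE]
  if (!nrow(calls)) {
    attr(empty, "scores") <- sc
    return(empty)
  }
  out <- data.frame(gene = calls$candidate, scope = "common",
                    calls[, c("ags_size", "k", "d_af", "mu_af", "sigma_af",
                              "z", "null_kind")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scores") <- sc
  out
}

#' Call patient-specific driver genes
#'
#' For each patient, the candidates are the FGS genes covered by that
#' patient's own filtered CNAs, and the AGS is that patient's extreme-
#' expression gene set; drivers are called at `z > z_threshold`.
#'
#' @param fgs output of [build_fgs()] (supplies the gene pool and per-patient
#'   alteration states).
#' @param patient_ags_list named list of [build_patient_ags()] data frames,
#'   one per patient.
#' @param network undirected igraph network.
#' @param z_threshold driver-calling threshold on z.
#' @param null_kind,seed,n_permutations passed to [nea_zscore()].
#' @return Data frame of calls: `gene`, `scope` (the patient id), NEA columns.
#' @export
call_patient_drivers <- function(fgs, patient_ags_list, network,
                                 z_threshold = 2,
                                 null_kind = "hypergeometric", seed = 1L,
                                 n_permutations = 1000) {
  alt <- fgs$alterations
  res <- list()
  for (p in names(patient_ags_list)) {
    cand <- intersect(fgs$genes, alt$gene[alt$patient == p])
    if (!length(cand)) next
    ags <- patient_ags_list[[p]]$gene
    sc <- nea_score_set(cand, ags, network, null_kind,
                        seed + match(p, names(patient_ags_list)) * 104729L,
                        n_permutations)
    calls <- sc[!is.na(sc$z) & sc$z > z_threshold, , drop = FALSE]
    if (!nrow(calls)) next
    res[[p]] <- data.frame(gene = calls$candidate, scope = p,
                           calls[, c("ags_size", "k", "d_af", "mu_af",
                                     "sigma_af", "z", "null_kind")],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene = character(), scope = character(),
                      ags_size = integer(), k = integer(), d_af = integer(),
                      mu_af = numeric(), sigma_af = numeric(), z = numeric(),
                      null_kind = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
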