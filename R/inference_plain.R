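# Plaintext reference pipeline: per-allele linear scores, top-2
# selection, sigmoid, and the homozygosity threshold rule. This is the
# oracle the fixed-point emulation is validated against.

#' Per-allele linear scores
#'
#' `score[k] = w_k . x + b_k` for every allele of the gene.
#'
#' @param model a `gene_model`.
#' @param x dosage vector over `model$snp_ids` (entries 0/1/2).
#' @return named numeric vector of scores, one per allele.
#' @export
linear_scores <- function(model, x) {
  if (length(x) != length(model$snp_ids))
    stop(sprintf("linear_scores: %d dosages vs %d model SNPs",
                 length(x), length(model$snp_ids)))
  drop(model$weights %*% x) + model$intercepts
}

#' Top-2 selection
#'
#' Indices of the two largest scores; ties break toward the lower allele
#' index so the result is deterministic.
#'
#' @param scores numeric vector (length >= 2).
#' @return list with `index_f`, `score_f`, `index_s`, `score_s`
#'   (`score_f >= score_s`, indices distinct).
#' @export
top2 <- function(scores) {
  if (length(scores) < 2L) stop("top2: need at least 2 scores")
  scores <- unname(scores)
  i1 <- which.max(scores)              # first maximum = lowest index on ties
  rest <- scores
  rest[i1] <- -Inf
  i2 <- which.max(rest)
  list(index_f = i1, score_f = scores[[i1]],
       index_s = i2, score_s = scores[[i2]])
}

#' Numerically stable logistic sigmoid
#'
#' @param x numeric.
#' @return 1 / (1 + exp(-x)), computed without overflow.
#' @export
sigmoid <- function(x) plogis(x)

#' Homozygosity threshold rule
#'
#' The call is homozygous `(af, af)` iff `pf >= ps * t` (boundary
#' included), else heterozygous `(af, as)`.
#'
#' @param pf,ps top-two probabilities, `pf >= ps`.
#' @param t integer threshold, >= 2.
#' @param af,as allele indices of the top-two scores.
#' @return list with `a1`, `a2` (allele indices; `a1` is always the
#'   top-scoring allele) and `homozygous`.
#' @export
threshold_decision <- function(pf, ps, t, af, as) {
  if (t < 2) stop("threshold_decision: t must be >= 2")
  hom <- pf >= ps * t
  list(a1 = af, a2 = if (hom) af else as, homozygous = hom)
}

#' Plaintext imputation of one sample's allele pair for one gene
#'
#' Linear scores -> top2 on the raw scores -> sigmoid on the two
#' survivors (sigmoid is strictly increasing, so the ordering is the
#' same either way) -> threshold rule.
#'
#' @param model a `gene_model` with `threshold_t` set.
#' @param x dosage vector over `model$snp_ids`.
#' @param reveal_probabilities also return `pf`/`ps` (off by default:
#'   the service model returns indices only).
#' @return list with `gene`, `a1`, `a2` (allele indices), `allele1`,
#'   `allele2` (names), `homozygous`; plus `pf`, `ps` if requested.
#' @export
impute_plain <- function(model, x, reveal_probabilities = FALSE) {
  if (is.na(model$threshold_t))
    stop("impute_plain: model threshold unset; run select_threshold (tune-threshold) first")
  tp <- top2(linear_scores(model, x))
  pf <- sigmoid(tp$score_f)
  ps <- sigmoid(tp$score_s)
  d <- threshold_decision(pf, ps, model$threshold_t, tp$index_f, tp$index_s)
  out <- list(gene = model$gene, a1 = d$a1, a2 = d$a2,
              allele1 = model$alleles[d$a1], allele2 = model$alleles[d$a2],
              homozygous = d$homozygous)
  if (reveal_probabilities) { out$pf <- pf; out$ps <- ps }
  out
}

#' Impute a cohort of samples for a set of gene models
#'
#' @param models named list of `gene_model`s.
#' @param dosage N x M dosage matrix (rownames = sample ids; columns must
#'   cover every model's `snp_ids`).
#' @param mode `"plain"` or `"he"` (fixed-point emulation path).
#' @param he_params a [fp_params()] (required for `mode = "he"`).
#' @param reveal_probabilities include pf/ps columns (plain mode only).
#' @return data.frame: sample, gene, allele1, allele2, mode
#'   (+ pf, ps when revealed).
#' @export
impute_cohort <- function(models, dosage, mode = c("plain", "he"),
                          he_params = NULL, reveal_probabilities = FALSE) {
  mode <- match.arg(mode)
  if (mode == "he" && is.null(he_params))
    stop("impute_cohort: he mode needs he_params (fp_params)")
  ids <- rownames(dosage)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dosage)))
  rows <- list()
  for (model in models) {
    missing_snps <- setdiff(model$snp_ids, colnames(dosage))
    if (length(missing_snps) > 0L) {
      message(sprintf("impute_cohort: skipping %s (%d model SNPs absent from target)",
                      model$gene, length(missing_snps)))
      next
    }
    X <- dosage[, model$snp_ids, drop = FALSE]
    for (i in seq_along(ids)) {
      r <- if (mode == "plain")
        impute_plain(model, X[i, ], reveal_probabilities = reveal_probabilities)
      else
        impute_he(model, X[i, ], he_params)
      row <- data.frame(sample = ids[i], gene = model$gene,
                        allele1 = r$allele1, allele2 = r$allele2,
                        mode = mode, stringsAsFactors = FALSE)
      if (reveal_probabilities && mode == "plain") {
        row$pf <- r$pf; row$ps <- r$ps
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("impute_cohort: no gene could be imputed on this target")
  do.call(rbind, rows)
}
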