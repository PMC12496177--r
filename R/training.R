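# One-vs-rest training: a ridge-penalized logistic regression per HLA
# allele on SNP dosages, plus grid selection of the homozygosity
# threshold t on a validation split.

#' Training configuration
#'
#' @param l2_lambda ridge penalty on the SNP weights (the intercept is
#'   never penalized). Default 1e-4: small enough to leave informative
#'   weights untouched, large enough to keep separated fits finite.
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the max absolute gradient.
#' @param seed seed for the validation split.
#' @param validation_fraction fraction of reference samples held out for
#'   threshold tuning when no explicit split is given.
#' @return list of class `train_config`.
#' @export
train_config <- function(l2_lambda = 1e-4, max_iter = 200L, tol = 1e-8,
                         seed = 1L, validation_fraction = 0.2) {
  stopifnot(l2_lambda >= 0, tol > 0, max_iter >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(l2_lambda = l2_lambda, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Binary presence labels for one allele
#'
#' `label[i] = 1` iff sample i carries at least one copy of the allele
#' (presence dosage >= 1); homozygotes are labelled 1, not 2 — presence
#' is binary.
#'
#' @param presence_dosage N x M_hla presence dosage matrix, columns named
#'   by marker id.
#' @param presence_markers marker table with `gene`, `allele` columns.
#' @param gene,allele which allele to label.
#' @return integer 0/1 vector over samples.
#' @export
extract_labels <- function(presence_dosage, presence_markers, gene, allele) {
  j <- which(presence_markers$gene == gene & presence_markers$allele == allele)
  if (length(j) != 1L)
    stop(sprintf("extract_labels: no unique presence marker for %s %s", gene, allele))
  as.integer(presence_dosage[, j] >= 1L)
}

#' Fit a single-allele ridge logistic regression
#'
#' Newton/IRLS maximization of the L2-penalized Bernoulli log-likelihood
#' with a sigmoid link; the intercept is unpenalized. Deterministic given
#' its inputs.
#'
#' @param X N x M dosage matrix (entries 0/1/2).
#' @param y binary response.
#' @param cfg a [train_config()].
#' @return list with `weights`, `intercept`, `converged`, `n_iter`.
#' @export
fit_allele_model <- function(X, y, cfg = train_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("fit_allele_model: constant labels (allele absent or fixed in panel)")
  n <- nrow(X); m <- ncol(X)
  Xd <- cbind(1, X)
  lam <- cfg$l2_lambda * c(0, rep(1, m))   # intercept unpenalized
  beta <- numeric(m + 1L)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(Xd, y - mu)) - lam * beta
    if (max(abs(grad)) < cfg$tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * w, Xd)
    diag(H) <- diag(H) + lam
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) step <- solve(H + diag(1e-8, m + 1L), grad)
    # halving keeps the penalized likelihood non-decreasing
    obj <- function(b) {
      e <- drop(Xd %*% b)
      sum(y * e - log1p(exp(pmin(e, 700)))) - sum(lam * b^2) / 2
    }
    f0 <- obj(beta)
    s <- 1
    repeat {
      bnew <- beta + s * step
      if (obj(bnew) >= f0 - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- bnew
  }
  if (!converged)
    warning(sprintf("fit_allele_model: not converged after %d iterations", cfg$max_iter))
  list(weights = beta[-1L], intercept = beta[1L],
       converged = converged, n_iter = it)
}

# intercept stand-in for alleles whose labels are constant: a large
# negative score keeps them from ever winning top2 against a fitted allele
.DEGENERATE_INTERCEPT <- -50

#' Fit all allele models for one gene
#'
#' One logistic regression per allele of the gene. Monomorphic SNPs are
#' dropped before fitting (with a warning); alleles whose labels are
#' constant in the training panel are retained with zero weights and a
#' large negative intercept, and flagged, so allele indices stay stable.
#'
#' @param snp_dosage N x M SNP dosage matrix (columns named by marker id).
#' @param presence_dosage,presence_markers presence dosages and their
#'   marker table (see [extract_labels()]).
#' @param gene gene name, e.g. `"HLA-A"`.
#' @param cfg a [train_config()].
#' @return object of class `gene_model`: `gene`, `alleles`, `weights`
#'   (K x M matrix), `intercepts`, `flagged`, `snp_ids`, `threshold_t`
#'   (NA until tuned), `bound_B` (fixed-point normalization bound).
#' @export
fit_gene_model <- function(snp_dosage, presence_dosage, presence_markers,
                           gene, cfg = train_config()) {
  sel <- presence_markers$gene == gene
  if (sum(sel) < 2L)
    stop(sprintf("fit_gene_model: gene %s has fewer than 2 alleles", gene))
  alleles <- presence_markers$allele[sel]
  pd <- presence_dosage[, sel, drop = FALSE]

  keep_snp <- apply(snp_dosage, 2, function(v) length(unique(v)) > 1L)
  if (any(!keep_snp))
    warning(sprintf("fit_gene_model: dropping %d monomorphic SNP(s)", sum(!keep_snp)))
  X <- snp_dosage[, keep_snp, drop = FALSE]
  snp_ids <- colnames(X)

  K <- length(alleles); M <- ncol(X)
  W <- matrix(0, K, M, dimnames = list(alleles, snp_ids))
  b <- rep(.DEGENERATE_INTERCEPT, K)
  flagged <- logical(K)
  for (k in seq_len(K)) {
    y <- as.integer(pd[, k] >= 1L)
    if (length(unique(y)) < 2L) { flagged[k] <- TRUE; next }
    fit <- fit_allele_model(X, y, cfg)
    W[k, ] <- fit$weights
    b[k] <- fit$intercept
    if (!fit$converged) flagged[k] <- TRUE
  }
  if (sum(!flagged) < 2L)
    stop(sprintf("fit_gene_model: gene %s has fewer than 2 trainable alleles", gene))

  scores <- W %*% t(X) + b          # K x N training scores
  bound_B <- max(abs(scores)) * 1.25
  structure(list(gene = gene, alleles = alleles, weights = W,
                 intercepts = b, flagged = flagged, snp_ids = snp_ids,
                 threshold_t = NA_integer_, bound_B = bound_B,
                 config = cfg),
            class = "gene_model")
}

#' Select the homozygosity threshold t on a validation split
#'
#' Runs the plaintext pipeline at every candidate t and returns the grid
#' value maximizing mean pair accuracy against the validation truth; ties
#' break toward the smallest t (most willing to call heterozygotes).
#'
#' @param model a `gene_model`.
#' @param val_dosage validation-sample SNP dosage matrix (columns must
#'   cover `model$snp_ids`).
#' @param val_truth data.frame with `sample`, `gene`, `allele1`, `allele2`
#'   (rownames of `val_dosage` are matched against `sample`).
#' @param grid candidate integer thresholds; default 2..20.
#' @return the model with `threshold_t` set and an attribute
#'   `validation_accuracy` (named vector over the grid).
#' @export
select_threshold <- function(model, val_dosage, val_truth, grid = 2:20) {
  stopifnot(length(grid) > 0)
  tr <- val_truth[val_truth$gene == model$gene, , drop = FALSE]
  ids <- intersect(rownames(val_dosage), tr$sample)
  if (length(ids) == 0L)
    stop("select_threshold: empty validation set for gene ", model$gene)
  X <- val_dosage[ids, model$snp_ids, drop = FALSE]
  scores <- model$weights %*% t(X) + model$intercepts  # K x n
  acc <- vapply(sort(as.integer(grid)), function(t) {
    m2 <- model; m2$threshold_t <- t
    hits <- vapply(seq_along(ids), function(i) {
      tp <- top2(scores[, i])
      pair <- threshold_decision(plogis(tp$score_f), plogis(tp$score_s), t,
                                 tp$index_f, tp$index_s)
      row <- tr[tr$sample == ids[i], ]
      pair_accuracy(c(row$allele1, row$allele2),
                    model$alleles[c(pair$a1, pair$a2)])
    }, 0)
    mean(hits)
  }, 0)
  grid_sorted <- sort(as.integer(grid))
  names(acc) <- grid_sorted
  best <- grid_sorted[which.max(acc)]   # which.max takes the first (smallest t) on ties
  model$threshold_t <- best
  attr(model, "validation_accuracy") <- acc
  model
}

#' Split sample ids into training and validation sets
#'
#' Seeded uniform split; explicit lists can be passed straight to the
#' trainers instead.
#'
#' @param sample_ids character vector.
#' @param cfg a [train_config()] (uses `seed` and `validation_fraction`).
#' @return list with `train` and `validation` id vectors (disjoint).
#' @export
split_samples <- function(sample_ids, cfg = train_config()) {
  n <- length(sample_ids)
  n_val <- max(1L, round(cfg$validation_fraction * n))
  set.seed(cfg$seed)
  val <- sort(sample(n, n_val))
  list(train = sample_ids[-val], validation = sample_ids[val])
}

#' Serialize gene models to a versioned JSON container
#'
#' @param models named list of `gene_model` objects (one per gene).
#' @param path output path.
#' @param he_params optional [fp_params()] stored alongside.
#' @export
write_model_container <- function(models, path, he_params = NULL) {
  enc <- lapply(models, function(m) {
    list(gene = m$gene, alleles = m$alleles, snp_ids = m$snp_ids,
         weights = unname(lapply(seq_len(nrow(m$weights)),
                                 function(k) unname(m$weights[k, ]))),
         intercepts = unname(m$intercepts), flagged = unname(m$flagged),
         threshold_t = m$threshold_t, bound_B = m$bound_B,
         provenance = list(l2_lambda = m$config$l2_lambda,
                           tol = m$config$tol, seed = m$config$seed))
  })
  obj <- list(format = "hlaimpute-model", version = 1L, genes = enc)
  if (!is.null(he_params)) obj$he_params <- unclass(he_params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model container written by [write_model_container()]
#'
#' @param path container path.
#' @return list with `models` (named list of `gene_model`) and
#'   `he_params` (a [fp_params()] or NULL).
#' @export
read_model_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hlaimpute-model"))
    stop("not an hlaimpute model container: ", path)
  models <- lapply(obj$genes, function(g) {
    W <- if (is.matrix(g$weights)) g$weights else do.call(rbind, g$weights)
    dimnames(W) <- list(g$alleles, g$snp_ids)
    structure(list(gene = g$gene, alleles = g$alleles, weights = W,
                   intercepts = g$intercepts, flagged = g$flagged,
                   snp_ids = g$snp_ids,
                   threshold_t = if (is.null(g$threshold_t)) NA_integer_
                                 else as.integer(g$threshold_t),
                   bound_B = g$bound_B, config = g$provenance),
              class = "gene_model")
  })
  names(models) <- vapply(models, `[[`, "", "gene")
  hp <- NULL
  if (!is.null(obj$he_params)) hp <- do.call(fp_params, as.list(obj$he_params))
  list(models = models, he_params = hp)
}
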