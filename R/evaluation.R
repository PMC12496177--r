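# Pair-accuracy scoring with P-group mapping, reference-panel allele
# frequencies, MAF-binned reporting.

#' Pair accuracy between a truth and a predicted allele pair
#'
#' `max(I(A1=B1) + I(A2=B2), I(A1=B2) + I(A2=B1)) / 2`: the better of
#' the two assignments of predicted to true alleles, so the score is
#' invariant to the storage order of either pair and takes values in
#' \{0, 0.5, 1\}.
#'
#' @param truth,pred character vectors of length 2 (allele names).
#' @return 0, 0.5 or 1.
#' @export
pair_accuracy <- function(truth, pred) {
  stopifnot(length(truth) == 2L, length(pred) == 2L,
            all(nzchar(truth)), all(nzchar(pred)))
  s1 <- (truth[1] == pred[1]) + (truth[2] == pred[2])
  s2 <- (truth[1] == pred[2]) + (truth[2] == pred[1])
  max(s1, s2) / 2
}

#' Map an allele pair to P-groups
#'
#' Each allele is replaced by its group when mapped, else left unchanged
#' (the mapping is the identity off its domain).
#'
#' @param pair character vector of length 2.
#' @param pgroup list from [read_pgroup_map()] (or `NULL` for identity).
#' @export
apply_pgroup <- function(pair, pgroup = NULL) {
  if (is.null(pgroup)) return(pair)
  mapped <- pgroup$map[pair]
  unname(ifelse(is.na(mapped), pair, mapped))
}

#' Reference-panel frequency of an HLA allele
#'
#' Count of presence over the 2N haplotypes, divided by 2N.
#'
#' @param presence_hap 2N x M_hla presence haplotype matrix.
#' @param presence_markers marker table for its columns.
#' @param gene,allele which allele.
#' @return frequency in `[0, 1]`.
#' @export
allele_frequency <- function(presence_hap, presence_markers, gene, allele) {
  j <- which(presence_markers$gene == gene & presence_markers$allele == allele)
  if (length(j) != 1L)
    stop(sprintf("allele_frequency: no unique presence marker for %s %s", gene, allele))
  sum(presence_hap[, j]) / nrow(presence_hap)
}

#' Frequency bin of an HLA allele
#'
#' Five left-closed bins: (1) MAF < 0.01, (2) 0.01 <= MAF < 0.05,
#' (3) 0.05 <= MAF < 0.1, (4) 0.1 <= MAF < 0.2, (5) MAF >= 0.2.
#'
#' @param freq frequency vector in `[0, 1]`.
#' @return integer bin index 1..5.
#' @export
maf_bin <- function(freq) {
  if (any(freq < 0 | freq > 1)) stop("maf_bin: frequency outside [0, 1]")
  findInterval(freq, c(0.01, 0.05, 0.1, 0.2)) + 1L
}

#' Score predictions against truth, per gene and per MAF bin
#'
#' Per-gene accuracy is the mean [pair_accuracy()] over scored
#' (sample, gene) records. Per-bin accuracy is allele-copy level: each
#' truth allele copy is "correct" iff it is matched under the assignment
#' that maximizes the pair-accuracy formula (identity assignment
#' preferred on ties), and bin accuracy is the proportion of correct
#' copies among truth copies whose allele falls in the bin. Records
#' whose truth or prediction contains a deprecated allele (per the
#' P-group table) are dropped from scoring and listed.
#'
#' @param truth `hla_truth` data.frame (sample, gene, allele1, allele2).
#' @param predictions data.frame from [impute_cohort()].
#' @param frequencies optional named list `gene -> named numeric vector`
#'   of allele frequencies (reference panel); enables per-bin reporting.
#' @param pgroup optional list from [read_pgroup_map()].
#' @return list of class `accuracy_report`: `per_gene` (gene, n,
#'   accuracy, error_pct), `per_bin` (bin, n_alleles, n_correct,
#'   accuracy), `per_sample`, `dropped` (excluded records), `n_scored`.
#' @export
evaluate_predictions <- function(truth, predictions, frequencies = NULL,
                                 pgroup = NULL) {
  key <- function(s, g) paste(s, g, sep = "\r")
  tk <- key(truth$sample, truth$gene)
  pk <- key(predictions$sample, predictions$gene)
  common <- intersect(tk, pk)
  if (length(common) == 0L)
    stop("evaluate_predictions: no (sample, gene) records shared by truth and predictions")

  dep <- if (is.null(pgroup)) character() else pgroup$deprecated
  per_sample <- list()
  dropped <- list()
  bin_tab <- data.frame(bin = 1:5, n_alleles = 0L, n_correct = 0L)

  for (k in common) {
    tr <- truth[match(k, tk), ]
    pr <- predictions[match(k, pk), ]
    t_pair <- c(tr$allele1, tr$allele2)
    p_pair <- c(pr$allele1, pr$allele2)
    if (any(t_pair %in% dep) || any(p_pair %in% dep)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(sample = tr$sample, gene = tr$gene,
                   reason = "deprecated allele", stringsAsFactors = FALSE)
      next
    }
    t_m <- apply_pgroup(t_pair, pgroup)
    p_m <- apply_pgroup(p_pair, pgroup)
    s1 <- (t_m[1] == p_m[1]) + (t_m[2] == p_m[2])
    s2 <- (t_m[1] == p_m[2]) + (t_m[2] == p_m[1])
    acc <- max(s1, s2) / 2
    # allele-copy correctness under the maximizing assignment
    # (identity first on ties)
    correct <- if (s1 >= s2)
      c(t_m[1] == p_m[1], t_m[2] == p_m[2])
    else
      c(t_m[1] == p_m[2], t_m[2] == p_m[1])
    per_sample[[length(per_sample) + 1L]] <-
      data.frame(sample = tr$sample, gene = tr$gene, accuracy = acc,
                 stringsAsFactors = FALSE)
    if (!is.null(frequencies) && tr$gene %in% names(frequencies)) {
      fr <- frequencies[[tr$gene]]
      for (j in 1:2) {
        f <- fr[t_pair[j]]
        if (is.na(f)) next
        b <- maf_bin(unname(f))
        bin_tab$n_alleles[b] <- bin_tab$n_alleles[b] + 1L
        bin_tab$n_correct[b] <- bin_tab$n_correct[b] + as.integer(correct[j])
      }
    }
  }
  if (length(per_sample) == 0L)
    stop("evaluate_predictions: every shared record was dropped")
  per_sample <- do.call(rbind, per_sample)
  per_gene <- do.call(rbind, lapply(split(per_sample, per_sample$gene), function(d)
    data.frame(gene = d$gene[1], n = nrow(d), accuracy = mean(d$accuracy),
               error_pct = 100 * (1 - mean(d$accuracy)),
               stringsAsFactors = FALSE)))
  rownames(per_gene) <- NULL
  bin_tab$accuracy <- ifelse(bin_tab$n_alleles > 0,
                             bin_tab$n_correct / bin_tab$n_alleles, NA_real_)
  structure(list(per_gene = per_gene,
                 per_bin = if (is.null(frequencies)) NULL else bin_tab,
                 per_sample = per_sample,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else NULL,
                 n_scored = nrow(per_sample)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("HLA imputation accuracy report:", x$n_scored, "scored records\n")
  print(x$per_gene, row.names = FALSE)
  if (!is.null(x$per_bin)) {
    cat("Per MAF bin (allele copies):\n")
    print(x$per_bin, row.names = FALSE)
  }
  if (!is.null(x$dropped))
    cat(nrow(x$dropped), "record(s) dropped (deprecated alleles)\n")
  invisible(x)
}

#' All allele frequencies of a reference panel, by gene
#'
#' @param panel an `hla_panel` (from [read_reference_panel()] or
#'   [simulate_panels()]).
#' @return named list: gene -> named frequency vector over its alleles.
#' @export
panel_frequencies <- function(panel) {
  pm <- panel$presence_markers
  freqs <- colSums(panel$presence) / nrow(panel$presence)
  lapply(split(seq_len(nrow(pm)), pm$gene), function(ix) {
    f <- freqs[ix]
    names(f) <- pm$allele[ix]
    f
  })
}
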