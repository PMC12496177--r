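# Synthetic reference/target panels with tag-SNP linkage. Each HLA
# allele is tagged by a characteristic SNP signature (its own block of
# tag SNPs), haplotypes carry the signature of their drawn allele with
# independent per-SNP flips, and diploid samples are pairs of
# haplotypes. This gives the strong local LD structure the imputation
# model relies on, with tunable noise and allele-frequency skew, at desk
# scale and with no external data.

#' Simulation configuration
#'
#' @param n_ref_samples,n_target_samples diploid sample counts for the
#'   reference and target panels.
#' @param genes named integer vector: gene name -> number of alleles,
#'   e.g. `c("HLA-A" = 6, "HLA-B" = 10)`.
#' @param tag_block_size tag SNPs per allele signature.
#' @param n_background_snps shared SNPs with no HLA linkage.
#' @param allele_freq_concentration symmetric-Dirichlet concentration
#'   for the allele frequency vectors; values below 1 skew toward a few
#'   common and many rare alleles, as observed for HLA.
#' @param noise_rate per-SNP haplotype flip probability (epsilon).
#' @param hom_enrichment probability that a sample's two haplotypes
#'   share the same allele draw at every gene (inbreeding-style knob so
#'   threshold tuning sees homozygotes). Default 0.1.
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @return list of class `sim_config` (includes the derived total
#'   `n_snps`).
#' @export
sim_config <- function(n_ref_samples = 600L, n_target_samples = 200L,
                       genes = c("HLA-A" = 6L, "HLA-B" = 10L),
                       tag_block_size = 4L, n_background_snps = 24L,
                       allele_freq_concentration = 0.35,
                       noise_rate = 0.01, hom_enrichment = 0.1,
                       seed = 1L) {
  stopifnot(n_ref_samples >= 1, n_target_samples >= 0,
            length(genes) >= 1, !is.null(names(genes)), all(genes >= 2),
            tag_block_size >= 1, n_background_snps >= 0,
            allele_freq_concentration > 0,
            noise_rate >= 0, noise_rate < 1,
            hom_enrichment >= 0, hom_enrichment <= 1)
  structure(list(n_ref_samples = as.integer(n_ref_samples),
                 n_target_samples = as.integer(n_target_samples),
                 genes = genes, tag_block_size = as.integer(tag_block_size),
                 n_background_snps = as.integer(n_background_snps),
                 n_snps = as.integer(sum(genes) * tag_block_size +
                                     n_background_snps),
                 allele_freq_concentration = allele_freq_concentration,
                 noise_rate = noise_rate, hom_enrichment = hom_enrichment,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# allele names follow the two-field convention; allele k of gene
# "HLA-A" is A*<k>:01, matching presence-marker id HLA_A_<k>01
.allele_names <- function(gene, K) {
  short <- sub("^HLA-", "", gene)
  sprintf("%s*%02d:01", short, seq_len(K))
}

# draws without reseeding, so callers control the RNG stream
.draw_pool <- function(cfg) {
  pool <- list()
  for (g in names(cfg$genes)) {
    K <- cfg$genes[[g]]
    gam <- rgamma(K, shape = cfg$allele_freq_concentration)
    while (sum(gam) == 0) gam <- rgamma(K, shape = cfg$allele_freq_concentration)
    freq <- gam / sum(gam)
    L <- K * cfg$tag_block_size
    sig <- matrix(0L, K, L)
    for (k in seq_len(K))
      sig[k, ((k - 1L) * cfg$tag_block_size + 1L):(k * cfg$tag_block_size)] <- 1L
    pool[[g]] <- list(alleles = .allele_names(g, K), freq = freq,
                      signatures = sig)
  }
  list(genes = pool,
       background_freq = if (cfg$n_background_snps > 0)
         runif(cfg$n_background_snps, 0.05, 0.95) else numeric())
}

#' Draw the allele pool: signatures and frequency vectors
#'
#' Each allele of each gene gets a distinct binary signature over its
#' own tag block; allele frequencies are a symmetric Dirichlet draw with
#' the configured concentration. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with per-gene `alleles`, `freq`, `signatures`
#'   (K x K*tag_block_size), and `background_freq`.
#' @export
simulate_haplotype_pool <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  .draw_pool(cfg)
}

# draws per-sample allele indices for every gene: a list gene -> N x 2
.draw_sample_alleles <- function(cfg, pool, n) {
  hom <- runif(n) < cfg$hom_enrichment
  out <- list()
  for (g in names(cfg$genes)) {
    K <- cfg$genes[[g]]
    a1 <- sample.int(K, n, replace = TRUE, prob = pool$genes[[g]]$freq)
    a2 <- sample.int(K, n, replace = TRUE, prob = pool$genes[[g]]$freq)
    a2[hom] <- a1[hom]
    out[[g]] <- cbind(a1, a2)
  }
  out
}

# builds the 2n x M SNP haplotype matrix from allele draws
.build_haplotypes <- function(cfg, pool, alleles_by_gene, n) {
  cols <- list()
  for (g in names(cfg$genes)) {
    sig <- pool$genes[[g]]$signatures
    idx <- as.vector(t(alleles_by_gene[[g]]))          # 2n draws, hap order
    h <- sig[idx, , drop = FALSE]
    if (cfg$noise_rate > 0) {
      flips <- matrix(rbinom(length(h), 1L, cfg$noise_rate), nrow(h), ncol(h))
      h <- (h + flips) %% 2L
    }
    cols[[g]] <- h
  }
  if (cfg$n_background_snps > 0) {
    bg <- matrix(rbinom(2L * n * cfg$n_background_snps, 1L,
                        rep(pool$background_freq, each = 2L * n)),
                 2L * n, cfg$n_background_snps)
    cols[["background"]] <- bg
  }
  m <- do.call(cbind, cols)
  storage.mode(m) <- "integer"
  m
}

# marker table for the simulated panel (chromosome 6 MHC coordinates)
.sim_markers <- function(cfg) {
  snp_ids <- sprintf("snp%05d", seq_len(cfg$n_snps))
  snp <- data.frame(id = snp_ids, pos = 29900000L + seq_len(cfg$n_snps) * 500L,
                    allele_a = "A", allele_b = "G", kind = "snp",
                    gene = NA_character_, allele = NA_character_,
                    stringsAsFactors = FALSE)
  hla <- do.call(rbind, lapply(names(cfg$genes), function(g) {
    K <- cfg$genes[[g]]
    short <- sub("^HLA-", "", g)
    data.frame(id = sprintf("HLA_%s_%02d01", short, seq_len(K)),
               pos = 30000000L + seq_len(K) * 100L,
               allele_a = "A", allele_b = "P", kind = "hla_presence",
               gene = g, allele = .allele_names(g, K),
               stringsAsFactors = FALSE)
  }))
  rbind(snp, hla)
}

#' Simulate a reference panel, target genotypes, and held-out truth
#'
#' The reference panel carries both SNP haplotypes and HLA presence
#' markers consistent with the drawn alleles (so the diploid-presence QC
#' keeps every sample); the target panel withholds the HLA markers and
#' is returned as diploid dosages with its truth table. Fully
#' deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `ref_panel` (class `hla_panel`), `target_dosage`
#'   (N x M integer matrix, rownames = sample ids), `truth`
#'   (`hla_truth` data.frame), `pool`, and `cfg`.
#' @export
simulate_panels <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  pool <- .draw_pool(cfg)
  markers <- .sim_markers(cfg)
  snp_markers <- markers[markers$kind == "snp", ]
  presence_markers <- markers[markers$kind == "hla_presence", ]

  build <- function(n, prefix) {
    alle <- .draw_sample_alleles(cfg, pool, n)
    hap <- .build_haplotypes(cfg, pool, alle, n)
    colnames(hap) <- snp_markers$id
    list(alleles = alle, hap = hap,
         ids = sprintf("%s%04d", prefix, seq_len(n)))
  }
  ref <- build(cfg$n_ref_samples, "ref")
  tgt <- build(cfg$n_target_samples, "tgt")

  # presence haplotypes: haplotype h of sample i carries allele
  # alleles[[g]][i, 1 or 2]
  presence <- matrix(0L, 2L * cfg$n_ref_samples, nrow(presence_markers),
                     dimnames = list(NULL, presence_markers$id))
  col0 <- 0L
  for (g in names(cfg$genes)) {
    K <- cfg$genes[[g]]
    idx <- as.vector(t(ref$alleles[[g]]))
    presence[cbind(seq_len(2L * cfg$n_ref_samples), col0 + idx)] <- 1L
    col0 <- col0 + K
  }

  ref_panel <- structure(list(sample_ids = ref$ids, snp = ref$hap,
                              presence = presence,
                              snp_markers = snp_markers,
                              presence_markers = presence_markers,
                              markers = markers),
                         class = "hla_panel")

  truth_table <- function(ids, alleles_by_gene) {
    do.call(rbind, lapply(names(cfg$genes), function(g) {
      an <- pool$genes[[g]]$alleles
      data.frame(sample = ids, gene = rep(g, length(ids)),
                 allele1 = an[alleles_by_gene[[g]][, 1]],
                 allele2 = an[alleles_by_gene[[g]][, 2]],
                 stringsAsFactors = FALSE)
    }))
  }
  truth <- truth_table(tgt$ids, tgt$alleles)
  class(truth) <- c("hla_truth", "data.frame")

  ref_truth <- truth_table(ref$ids, ref$alleles)
  class(ref_truth) <- c("hla_truth", "data.frame")

  list(ref_panel = ref_panel,
       target_dosage = haplotypes_to_dosage(tgt$hap, tgt$ids),
       target_hap = tgt$hap, target_ids = tgt$ids,
       truth = truth, ref_truth = ref_truth, pool = pool, cfg = cfg)
}

#' Train per-gene models on a simulated (or loaded) panel
#'
#' Convenience wrapper: splits reference samples, fits every gene, and
#' tunes the homozygosity threshold on the validation split.
#'
#' @param sim output of [simulate_panels()] (or an equivalent list with
#'   `ref_panel` and `ref_truth`).
#' @param cfg a [train_config()].
#' @param grid threshold grid, default 2..20.
#' @return named list of tuned `gene_model`s.
#' @export
train_from_panel <- function(sim, cfg = train_config(), grid = 2:20) {
  panel <- sim$ref_panel
  ids <- panel$sample_ids
  sp <- split_samples(ids, cfg)
  hap_rows <- function(samples) {
    i <- match(samples, ids)
    sort(c(2L * i - 1L, 2L * i))
  }
  tr_rows <- hap_rows(sp$train); va_rows <- hap_rows(sp$validation)
  snp_dos_tr <- haplotypes_to_dosage(panel$snp[tr_rows, , drop = FALSE], sp$train)
  snp_dos_va <- haplotypes_to_dosage(panel$snp[va_rows, , drop = FALSE], sp$validation)
  pres_dos_tr <- haplotypes_to_dosage(panel$presence[tr_rows, , drop = FALSE], sp$train)
  val_truth <- sim$ref_truth[sim$ref_truth$sample %in% sp$validation, ]

  models <- list()
  for (g in unique(panel$presence_markers$gene)) {
    m <- fit_gene_model(snp_dos_tr, pres_dos_tr, panel$presence_markers, g, cfg)
    m <- select_threshold(m, snp_dos_va, val_truth, grid)
    models[[g]] <- m
  }
  models
}
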