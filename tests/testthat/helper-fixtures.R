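# Shared fixtures: tiny hand-written panels and toy fixed-point
# parameter sets used across the test files.

# a 3-SNP, 2-allele, 2-sample panel written to disk in the SNP2HLA
# dialect; returns the paths plus the matrices that went in
write_toy_panel <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  markers <- data.frame(
    id = c("rs1", "rs2", "rs3", "HLA_A_0101", "HLA_A_0201"),
    pos = c(100L, 200L, 300L, 1000L, 1100L),
    allele_a = c("A", "C", "G", "A", "A"),
    allele_b = c("G", "T", "A", "P", "P"),
    kind = c("snp", "snp", "snp", "hla_presence", "hla_presence"),
    stringsAsFactors = FALSE)
  # samples: S1 = A*01:01 het A*02:01, S2 = A*01:01 homozygote
  hap <- rbind(
    c(1L, 0L, 1L, 1L, 0L),   # S1 hap1
    c(0L, 1L, 0L, 0L, 1L),   # S1 hap2
    c(1L, 0L, 1L, 1L, 0L),   # S2 hap1
    c(1L, 1L, 0L, 1L, 0L))   # S2 hap2
  mp <- file.path(dir, "toy.markers")
  bp <- file.path(dir, "toy.bgl.phased")
  write_panel(markers, hap, c("S1", "S2"), mp, bp)
  list(markers_path = mp, bgl_path = bp, markers = markers, hap = hap,
       sample_ids = c("S1", "S2"))
}

# toy modulus parameter sets for the circuit tests
toy_params <- function(Q = 2^10) fp_params(Q = Q, scale = 2, B = 1, T_norm = -1,
                                           lut_size = 256, pack_size = 4)

# default-precision parameters with a generic score bound
default_params <- function(B = 10) fp_params(B = B, T_norm = -B)

# deterministic small simulated study shared by several files (cached
# per session to keep the suite fast)
.shared_sim_env <- new.env()
shared_sim <- function() {
  if (is.null(.shared_sim_env$sim)) {
    .shared_sim_env$sim <- simulate_panels(sim_config(
      n_ref_samples = 400L, n_target_samples = 120L,
      genes = c("HLA-A" = 5L, "HLA-B" = 7L), seed = 42L))
    .shared_sim_env$models <- train_from_panel(.shared_sim_env$sim,
                                               train_config(seed = 42L))
  }
  list(sim = .shared_sim_env$sim, models = .shared_sim_env$models)
}
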