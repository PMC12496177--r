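# Bit-faithful plaintext emulation of the encrypted evaluation path.
# All "torus" values are integers in [0, Q) stored as doubles (Q defaults
# to 2^32, well inside the 2^53 exact-integer range); arithmetic is
# modulo Q. The emulation reproduces the integer semantics of the
# server-side circuits -- fixed-point scale encoding, chunked linear
# accumulation, normalization to [0, Q/4], cmpbit/mux max-min selection,
# a look-up-table sigmoid standing in for programmable bootstrapping,
# and division-by-t thresholding -- without cryptographic noise.

#' Fixed-point parameters for the emulated encrypted pipeline
#'
#' @param Q ciphertext modulus (power of two). Default 2^32.
#' @param scale fixed-point encoding factor: reals are multiplied by
#'   `scale` and rounded. Default 2^20 (precision 2^-21).
#' @param B expected bound for linear scores; scores above `B` clamp.
#' @param T_norm lower normalization threshold (scores at or below it
#'   map to 0). Default `-B`.
#' @param lut_size number of table entries for the sigmoid look-up
#'   (power of two). Default 2048.
#' @param pack_size SNPs accumulated per ciphertext chunk. Default 2048.
#' @return list of class `fp_params`.
#' @export
fp_params <- function(Q = 2^32, scale = 2^20, B = 10, T_norm = -B,
                      lut_size = 2048L, pack_size = 2048L) {
  is_pow2 <- function(x) x >= 2 && abs(log2(x) - round(log2(x))) < 1e-9
  stopifnot(is_pow2(Q), scale > 0, T_norm < B, is_pow2(lut_size),
            pack_size >= 1)
  structure(list(Q = Q, scale = scale, B = B, T_norm = T_norm,
                 lut_size = as.numeric(lut_size),
                 pack_size = as.numeric(pack_size)),
            class = "fp_params")
}

#' Fixed-point parameters matched to a trained gene model
#'
#' Uses the model's stored score bound for `B` (estimated on the training
#' panel with a 1.25x safety factor) and `T_norm = -B`.
#'
#' @param model a `gene_model`.
#' @param ... overrides passed to [fp_params()].
#' @export
fp_params_for_model <- function(model, ...) {
  fp_params(B = model$bound_B, T_norm = -model$bound_B, ...)
}

# signed representative of a torus residue: value in [-Q/2, Q/2)
signed_torus <- function(x, Q) {
  v <- x %% Q
  ifelse(v >= Q / 2, v - Q, v)
}

#' Encode a real value as a torus residue
#'
#' `round(v * scale) mod Q`; negative values wrap. Errors when
#' `|v| * scale >= Q/2` (the value would alias).
#'
#' @param v numeric vector.
#' @param p an [fp_params()].
#' @return numeric vector of residues in `[0, Q)`.
#' @export
encode_fixed <- function(v, p) {
  if (any(abs(v) * p$scale >= p$Q / 2))
    stop("encode_fixed: value overflows the fixed-point range |v|*scale < Q/2")
  round(v * p$scale) %% p$Q
}

#' Decode a torus residue back to a real value
#'
#' Inverse of [encode_fixed()] to within `1/(2*scale)`.
#'
#' @param tv residue vector in `[0, Q)`.
#' @param p an [fp_params()].
#' @export
decode_fixed <- function(tv, p) signed_torus(tv, p$Q) / p$scale

#' Emulated encrypted linear function
#'
#' Per-allele fixed-point dot product between rounded-and-scaled weights
#' and integer SNP dosages, accumulated chunk-by-chunk in marker order
#' (`pack_size` SNPs per chunk, emulating one packed ciphertext per
#' chunk), modulo Q, plus the encoded intercept. Integer accumulation is
#' exact, so the chunking never changes the result.
#'
#' @param model a `gene_model`.
#' @param x dosage vector over `model$snp_ids`.
#' @param p an [fp_params()].
#' @return numeric vector of residues, one per allele.
#' @export
linear_he <- function(model, x, p) {
  if (length(x) != length(model$snp_ids))
    stop("linear_he: dosage length mismatch")
  Wq <- round(model$weights * p$scale)
  bq <- round(model$intercepts * p$scale)
  M <- length(x)
  # exact (unreduced) total for the overflow check
  total <- drop(Wq %*% x) + bq
  if (any(abs(total) >= p$Q / 2))
    stop("linear_he: accumulated score overflows Q/2; increase Q or reduce scale")
  acc <- rep(0, nrow(Wq))
  starts <- seq(1L, M, by = p$pack_size)
  for (s in starts) {
    e <- min(s + p$pack_size - 1L, M)
    acc <- (acc + drop(Wq[, s:e, drop = FALSE] %*% x[s:e])) %% p$Q
  }
  (acc + bq) %% p$Q
}

#' Normalize a real score onto the quarter torus
#'
#' `0` for `x <= T_norm`, else `round(Q/4 * (x - T_norm)/(B - T_norm))`;
#' scores above `B` are clamped to `B` (counted, reported via message).
#' Maps `[T_norm, B]` onto `[0, Q/4]`, non-decreasing.
#'
#' @param x numeric score vector.
#' @param p an [fp_params()].
#' @return integer-valued numeric vector in `[0, Q/4]`.
#' @export
normalize_t <- function(x, p) {
  n_clamp <- sum(x > p$B)
  if (n_clamp > 0L) {
    message(sprintf("normalize_t: clamped %d score(s) above B = %g", n_clamp, p$B))
    x <- pmin(x, p$B)
  }
  ifelse(x <= p$T_norm, 0,
         round(p$Q / 4 * (x - p$T_norm) / (p$B - p$T_norm)))
}

# inverse of the normalization map on (0, Q/4]; used to build the
# sigmoid look-up table
normalize_inv <- function(tv, p) p$T_norm + (p$B - p$T_norm) * tv / (p$Q / 4)

#' Comparison bit
#'
#' `Q/2` iff the signed interpretation of `x` (in `[-Q/2, Q/2)`) is
#' `>= 0`, else `0`. `ctc = cmpbit(a - b)` encodes "a >= b".
#'
#' @param x residue vector (any integers; reduced mod Q).
#' @param p an [fp_params()].
#' @export
cmpbit <- function(x, p) ifelse(signed_torus(x, p$Q) >= 0, p$Q / 2, 0)

#' Conditional pass (multiplexer primitive)
#'
#' `x - Q/2` if `x >= Q/2`, else `0`. Together with [cmpbit()] it
#' realizes selection: `mux(ctc + a) + mux(Q/2 - ctc + b)` equals `a`
#' when `ctc = Q/2` and `b` when `ctc = 0`, provided both payloads are
#' below `Q/4`.
#'
#' @param x residue vector (reduced mod Q).
#' @param p an [fp_params()].
#' @export
mux <- function(x, p) {
  v <- x %% p$Q
  ifelse(v >= p$Q / 2, v - p$Q / 2, 0)
}

#' An indexed torus value (payload for the selection circuits)
#'
#' The allele index rides through the same ctc-controlled mux identities
#' as the score, so the circuits return encrypted indices.
#'
#' @param value residue in `[0, Q/4)` (a normalized score or encoded
#'   probability).
#' @param index allele index (small non-negative integer).
#' @export
indexed_value <- function(value, index) list(value = value, index = index)

# the shared ctc-controlled selection identity, applied to any payload
.mux_select <- function(ctc, pa, pb, p) {
  mux(ctc + pa, p) + mux(p$Q / 2 - ctc + pb, p)
}

#' Emulated encrypted max of two indexed values
#'
#' `max(a, b) = mux(ctc + a) + mux(Q/2 - ctc + b)` with
#' `ctc = cmpbit(a - b)`; the index payload is selected by the same
#' identity. On ties (`a = b`) the left argument wins (`cmpbit(0) = Q/2`).
#'
#' @param a,b [indexed_value()]s with values in `[0, Q/4)`.
#' @param p an [fp_params()].
#' @export
he_max <- function(a, b, p) {
  if (a$value >= p$Q / 4 || b$value >= p$Q / 4 || a$value < 0 || b$value < 0)
    stop("he_max: values must lie in [0, Q/4) (normalize first)")
  ctc <- cmpbit(a$value - b$value, p)
  indexed_value(.mux_select(ctc, a$value, b$value, p),
                .mux_select(ctc, a$index, b$index, p))
}

#' Emulated encrypted min of two indexed values
#'
#' `min(a, b) = a + b - max(a, b)` (mod Q); the index payload takes the
#' complementary branch of the selection identity.
#'
#' @inheritParams he_max
#' @export
he_min <- function(a, b, p) {
  if (a$value >= p$Q / 4 || b$value >= p$Q / 4 || a$value < 0 || b$value < 0)
    stop("he_min: values must lie in [0, Q/4) (normalize first)")
  ctc <- cmpbit(a$value - b$value, p)
  mx <- .mux_select(ctc, a$value, b$value, p)
  indexed_value((a$value + b$value - mx) %% p$Q,
                .mux_select(p$Q / 2 - ctc, a$index, b$index, p))
}

#' Emulated encrypted top-2 selection
#'
#' Sequential scan maintaining a running (top, second) pair with
#' [he_max()]/[he_min()] at each step. When all values are distinct the
#' decoded indices equal the plaintext [top2()] result; ties resolve
#' toward the earlier index, matching the plaintext tie-break.
#'
#' @param values list of [indexed_value()]s (length >= 2, values in
#'   `[0, Q/4)`).
#' @param p an [fp_params()].
#' @return list with `first`, `second` ([indexed_value()]s,
#'   `first$value >= second$value`).
#' @export
he_top2 <- function(values, p) {
  if (length(values) < 2L) stop("he_top2: need at least 2 values")
  top <- he_max(values[[1]], values[[2]], p)
  second <- he_min(values[[1]], values[[2]], p)
  for (v in values[-(1:2)]) {
    new_top <- he_max(top, v, p)
    loser <- he_min(top, v, p)
    top <- new_top
    second <- he_max(second, loser, p)
  }
  list(first = top, second = second)
}

# build (and memoize per parameter set) the sigmoid look-up table:
# entry i holds the fixed-point encoding of sigmoid(normalize_inv(center
# of cell i)), emulating the test vector of a programmable bootstrap
.lut_cache <- new.env(parent = emptyenv())
.sigmoid_lut <- function(p) {
  key <- paste(p$Q, p$scale, p$B, p$T_norm, p$lut_size, sep = "/")
  if (!is.null(.lut_cache[[key]])) return(.lut_cache[[key]])
  cell <- (p$Q / 4) / p$lut_size
  centers <- ((seq_len(p$lut_size) - 1) + 0.5) * cell
  tab <- encode_fixed(plogis(normalize_inv(centers, p)), p)
  .lut_cache[[key]] <- tab
  tab
}

#' Look-up-table sigmoid on a normalized score
#'
#' Evaluates `sigmoid(normalize^-1(.))` through a `lut_size`-entry table
#' indexed by the top bits of the input (emulating programmable
#' bootstrapping). The absolute error against the exact composition is
#' bounded by `max-slope * cell-width + 1/(2*scale)`, with cell width
#' `(B - T_norm)/lut_size` in score units and max slope 1/4.
#'
#' @param tv residue(s) in `[0, Q/4]` (output of [normalize_t()]).
#' @param p an [fp_params()].
#' @return residue(s) encoding probabilities in (0, 1) at `scale`.
#' @export
lut_sigmoid <- function(tv, p) {
  if (any(tv < 0 | tv > p$Q / 4))
    stop("lut_sigmoid: input outside [0, Q/4]")
  tab <- .sigmoid_lut(p)
  cell <- (p$Q / 4) / p$lut_size
  idx <- pmin(floor(tv / cell), p$lut_size - 1)  # top bits of tv
  tab[idx + 1]
}

#' Emulated encrypted thresholding
#'
#' Instead of comparing `pf` with `ps * t` (which could overflow), the
#' encoded `pf` is divided by `t` (round-to-nearest) and compared with
#' `ps`: `ctc = cmpbit(round(pf/t) - ps)`. The second allele index is
#' selected by the mux identity on the index payloads; the first always
#' equals the top allele, so it needs no circuit.
#'
#' @param pf,ps [indexed_value()]s whose values encode the top-two
#'   probabilities (`pf$value >= ps$value` as signed).
#' @param t integer threshold >= 2.
#' @param p an [fp_params()].
#' @return list with `a1`, `a2` (decoded allele indices) and
#'   `homozygous`.
#' @export
he_threshold <- function(pf, ps, t, p) {
  if (t < 2) stop("he_threshold: t must be >= 2")
  ctc <- cmpbit(round(pf$value / t) - ps$value, p)
  a2 <- .mux_select(ctc, pf$index, ps$index, p)
  list(a1 = pf$index, a2 = a2, homozygous = ctc == p$Q / 2)
}

#' Imputation through the emulated encrypted pipeline
#'
#' Chunked fixed-point linear scores, normalization onto the quarter
#' torus, cmpbit/mux top-2 selection carrying allele indices, LUT
#' sigmoid on the two survivors, and division-by-t thresholding. The
#' returned indices are decoded at the end; everything upstream is the
#' integer arithmetic the encrypted server would perform.
#'
#' @param model a `gene_model` with `threshold_t` set.
#' @param x dosage vector over `model$snp_ids`.
#' @param p an [fp_params()]; use [fp_params_for_model()] to match the
#'   model's score bound.
#' @return list with `gene`, `a1`, `a2`, `allele1`, `allele2`,
#'   `homozygous` (same shape as [impute_plain()]).
#' @export
impute_he <- function(model, x, p = fp_params_for_model(model)) {
  if (is.na(model$threshold_t))
    stop("impute_he: model threshold unset; run select_threshold (tune-threshold) first")
  tv <- linear_he(model, x, p)
  scores <- unname(decode_fixed(tv, p))
  norm <- normalize_t(scores, p)
  # selection circuits require payloads strictly below Q/4; a score
  # clamped at exactly B lands on Q/4 and is pulled back one unit
  norm <- pmin(norm, p$Q / 4 - 1)
  vals <- lapply(seq_along(norm), function(k) indexed_value(norm[k], k))
  tp <- he_top2(vals, p)
  pf <- indexed_value(lut_sigmoid(tp$first$value, p), tp$first$index)
  ps <- indexed_value(lut_sigmoid(tp$second$value, p), tp$second$index)
  d <- he_threshold(pf, ps, model$threshold_t, p)
  list(gene = model$gene, a1 = d$a1, a2 = d$a2,
       allele1 = model$alleles[d$a1], allele2 = model$alleles[d$a2],
       homozygous = d$homozygous)
}
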