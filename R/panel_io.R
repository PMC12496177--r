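# Readers/writers for the SNP2HLA-dialect reference/target panels:
# a whitespace markers file (id pos alleleA alleleB) and a Beagle-v3
# phased file ("I id" header, "M <marker>" rows, one column per haplotype).
# HLA alleles travel as binary presence pseudo-markers named HLA_<GENE>_<digits>.

#' Parse an HLA presence-marker id into gene and two-field allele names
#'
#' Ids follow the SNP2HLA convention `HLA_<GENE>_<4-6 digits>`, e.g.
#' `HLA_A_0101` encodes gene `HLA-A`, allele `A*01:01`. Ids that do not
#' match the convention are kept verbatim and flagged.
#'
#' @param id character vector of marker ids.
#' @return data.frame with columns `id`, `gene`, `allele`, `parsed` (logical).
#' @export
parse_hla_marker_id <- function(id) {
  m <- regmatches(id, regexec("^HLA_([A-Z0-9]+)_([0-9]{4,6})$", id))
  gene <- allele <- rep(NA_character_, length(id))
  parsed <- vapply(m, length, 1L) == 3L
  for (i in which(parsed)) {
    g <- m[[i]][2]; d <- m[[i]][3]
    gene[i] <- paste0("HLA-", g)
    # split digit string into two fields: first 2 digits, remainder
    allele[i] <- sprintf("%s*%s:%s", g, substr(d, 1, 2), substr(d, 3, nchar(d)))
  }
  unparsed <- !parsed
  gene[unparsed] <- NA_character_
  allele[unparsed] <- id[unparsed]   # kept verbatim
  data.frame(id = id, gene = gene, allele = allele, parsed = parsed,
             stringsAsFactors = FALSE)
}

#' Read a SNP2HLA-dialect markers file
#'
#' Whitespace-delimited, four columns: id, position (1-based bp), alleleA,
#' alleleB. Ids beginning `HLA_` are classified as binary HLA presence
#' markers, everything else as SNPs.
#'
#' @param path path to the markers file.
#' @return data.frame with columns `id`, `pos`, `allele_a`, `allele_b`,
#'   `kind` (`"snp"` or `"hla_presence"`), plus `gene`/`allele` for
#'   presence markers.
#' @export
read_markers <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), pos = integer(),
                      allele_a = character(), allele_b = character(),
                      kind = character(), gene = character(),
                      allele = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 4L)
  if (length(bad) > 0L)
    stop(sprintf("markers file %s: malformed line %d (expected 4 fields)",
                 path, bad[1]))
  id <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos))
    stop(sprintf("markers file %s: non-integer position at line %d",
                 path, which(is.na(pos))[1]))
  if (anyDuplicated(id))
    stop(sprintf("markers file %s: duplicate marker id '%s'",
                 path, id[duplicated(id)][1]))
  kind <- ifelse(startsWith(id, "HLA_"), "hla_presence", "snp")
  out <- data.frame(id = id, pos = pos,
                    allele_a = vapply(fields, `[[`, "", 3L),
                    allele_b = vapply(fields, `[[`, "", 4L),
                    kind = kind, stringsAsFactors = FALSE)
  ann <- parse_hla_marker_id(out$id)
  out$gene <- ifelse(kind == "hla_presence", ann$gene, NA_character_)
  out$allele <- ifelse(kind == "hla_presence", ann$allele, NA_character_)
  out
}

#' Read a Beagle-v3 phased haplotype file
#'
#' Rows are markers (`M <id> <2N allele calls>`), the header row
#' (`I id <sample repeated twice>`) names samples; columns (2i-1, 2i)
#' are the two haplotypes of sample i. Allele characters are mapped to
#' 0/1 against each marker's declared alleleA/alleleB; for HLA presence
#' markers `A` (absent) is 0 and `P` (present) is 1.
#'
#' @param markers data.frame from [read_markers()].
#' @param path path to the phased file.
#' @return list with `sample_ids`, `snp` (haplotype matrix 2N x M_snp,
#'   columns named by marker id), `presence` (2N x M_hla), and the marker
#'   subsets `snp_markers`, `presence_markers`.
#' @export
read_bgl_phased <- function(markers, path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  types <- vapply(fields, `[[`, "", 1L)
  hdr <- which(types == "I")
  if (length(hdr) != 1L)
    stop(sprintf("phased file %s: expected exactly one 'I id' header row", path))
  hcols <- fields[[hdr]][-(1:2)]
  if (length(hcols) %% 2L != 0L)
    stop(sprintf("phased file %s: odd haplotype column count (%d)",
                 path, length(hcols)))
  n <- length(hcols) %/% 2L
  sample_ids <- if (n == 0L) character() else hcols[seq(1L, 2L * n, by = 2L)]
  if (n > 0L && !identical(sample_ids, hcols[seq(2L, 2L * n, by = 2L)]))
    stop(sprintf("phased file %s: header sample ids not repeated in pairs", path))

  mrows <- which(types == "M")
  row_ids <- vapply(fields[mrows], `[[`, "", 2L)
  midx <- match(row_ids, markers$id)
  if (anyNA(midx))
    stop(sprintf("phased file %s: marker '%s' absent from markers file",
                 path, row_ids[is.na(midx)][1]))

  hap <- matrix(0L, nrow = 2L * n, ncol = length(mrows),
                dimnames = list(NULL, row_ids))
  for (j in seq_along(mrows)) {
    calls <- fields[[mrows[j]]][-(1:2)]
    if (length(calls) != 2L * n)
      stop(sprintf("phased file %s: marker '%s' has %d calls, expected %d",
                   path, row_ids[j], length(calls), 2L * n))
    mk <- markers[midx[j], ]
    # presence pseudo-markers are coded by character: P carries, A does
    # not, whichever order the markers file declares them in
    v <- if (mk$kind == "hla_presence")
      ifelse(calls == "P", 1L, ifelse(calls == "A", 0L, NA_integer_))
    else
      ifelse(calls == mk$allele_b, 1L, ifelse(calls == mk$allele_a, 0L, NA_integer_))
    if (anyNA(v))
      stop(sprintf("phased file %s: marker '%s' call '%s' matches neither allele (%s/%s)",
                   path, mk$id, calls[is.na(v)][1], mk$allele_a, mk$allele_b))
    hap[, j] <- v
  }
  kind <- markers$kind[midx]
  list(sample_ids = sample_ids,
       snp = hap[, kind == "snp", drop = FALSE],
       presence = hap[, kind == "hla_presence", drop = FALSE],
       snp_markers = markers[midx[kind == "snp"], , drop = FALSE],
       presence_markers = markers[midx[kind == "hla_presence"], , drop = FALSE])
}

#' Read a full reference panel (markers + phased haplotypes)
#'
#' @param markers_path,bgl_path paths to the markers and phased files.
#' @return an object of class `hla_panel`: the [read_bgl_phased()] list
#'   plus the complete `markers` table.
#' @export
read_reference_panel <- function(markers_path, bgl_path) {
  markers <- read_markers(markers_path)
  p <- read_bgl_phased(markers, bgl_path)
  p$markers <- markers
  class(p) <- "hla_panel"
  p
}

#' Collapse phased haplotypes to diploid dosages
#'
#' `dosage[i, m] = hap[2i-1, m] + hap[2i-1 + 1, m]`, the count of alleleB
#' copies carried by sample i.
#'
#' @param hap 2N x M haplotype matrix over \{0,1\}.
#' @param sample_ids optional sample names for the rows of the result.
#' @return N x M integer matrix over \{0,1,2\}.
#' @export
haplotypes_to_dosage <- function(hap, sample_ids = NULL) {
  if (nrow(hap) %% 2L != 0L) stop("haplotype matrix must have an even row count")
  n <- nrow(hap) %/% 2L
  odd <- 2L * seq_len(n) - 1L
  d <- hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
  storage.mode(d) <- "integer"
  if (!is.null(sample_ids)) rownames(d) <- sample_ids
  d
}

#' Diploid-presence QC filter
#'
#' A sample passes iff, for every HLA gene, the sum of its presence-marker
#' dosages over that gene's alleles is exactly 2 (one allele per
#' chromosome; a homozygote contributes a single dosage of 2).
#'
#' @param presence_dosage N x M_hla dosage matrix of the presence markers
#'   (rownames = sample ids).
#' @param presence_markers marker table for those columns (needs `gene`).
#' @return list with `kept` and `removed` character vectors of sample ids.
#' @export
qc_diploid_presence <- function(presence_dosage, presence_markers) {
  ids <- rownames(presence_dosage)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(presence_dosage)))
  genes <- unique(presence_markers$gene)
  ok <- rep(TRUE, nrow(presence_dosage))
  for (g in genes) {
    cols <- which(presence_markers$gene == g)
    sums <- rowSums(presence_dosage[, cols, drop = FALSE])
    ok <- ok & (sums == 2L)
  }
  list(kept = ids[ok], removed = ids[!ok])
}

#' Read an HLA truth table
#'
#' Tab-separated with header columns `sample`, `gene`, `allele1`,
#' `allele2`; pairs are unordered.
#'
#' @param path path to the TSV.
#' @return data.frame of class `hla_truth`.
#' @export
read_hla_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "gene", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("truth table %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  key <- paste(df$sample, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("truth table %s: duplicate (sample, gene) entry '%s / %s'",
                 path, df$sample[duplicated(key)][1], df$gene[duplicated(key)][1]))
  if (nrow(df) > 0L && any(!nzchar(df$allele1) | !nzchar(df$allele2)))
    stop(sprintf("truth table %s: empty allele name", path))
  df <- df[, need, drop = FALSE]
  class(df) <- c("hla_truth", "data.frame")
  df
}

#' Recover per-sample HLA truth from presence dosages
#'
#' For QC-passed samples every gene has presence dosages summing to 2,
#' so the allele pair can be read off directly (a dosage of 2 is a
#' homozygote). Samples failing that invariant for a gene are skipped.
#'
#' @param presence_dosage N x M_hla dosage matrix (rownames = sample ids).
#' @param presence_markers marker table with `gene`, `allele`.
#' @return `hla_truth` data.frame (sample, gene, allele1, allele2).
#' @export
truth_from_presence <- function(presence_dosage, presence_markers) {
  ids <- rownames(presence_dosage)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(presence_dosage)))
  rows <- list()
  for (g in unique(presence_markers$gene)) {
    cols <- which(presence_markers$gene == g)
    alleles <- presence_markers$allele[cols]
    d <- presence_dosage[, cols, drop = FALSE]
    for (i in seq_along(ids)) {
      v <- d[i, ]
      if (sum(v) != 2L) next
      carried <- rep(alleles, v)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = ids[i], gene = g,
                   allele1 = carried[1], allele2 = carried[2],
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sample = character(), gene = character(),
                         allele1 = character(), allele2 = character(),
                         stringsAsFactors = FALSE)
  class(out) <- c("hla_truth", "data.frame")
  out
}

#' Read a P-group mapping table
#'
#' Tab-separated `allele`, `group`; optional logical column `deprecated`
#' marking alleles whose records are excluded from scoring.
#'
#' @param path path to the TSV.
#' @return list with `map` (named character vector) and `deprecated`
#'   (character vector of allele names).
#' @export
read_pgroup_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "group") %in% names(df)))
    stop(sprintf("P-group table %s: need columns allele, group", path))
  dep <- character()
  if ("deprecated" %in% names(df))
    dep <- df$allele[as.logical(df$deprecated) %in% TRUE]
  map <- df$group
  names(map) <- df$allele
  list(map = map, deprecated = dep)
}

#' Write a reference panel in the SNP2HLA dialect
#'
#' Emits a markers file and a Beagle-v3 phased file that read back
#' bit-identically through [read_markers()]/[read_bgl_phased()].
#'
#' @param markers marker table (id, pos, allele_a, allele_b, kind).
#' @param hap 2N x M haplotype matrix, columns aligned with `markers`.
#' @param sample_ids length-N sample names.
#' @param markers_path,bgl_path output paths.
#' @export
write_panel <- function(markers, hap, sample_ids, markers_path, bgl_path) {
  if (ncol(hap) != nrow(markers))
    stop(sprintf("write_panel: %d haplotype columns vs %d markers",
                 ncol(hap), nrow(markers)))
  if (nrow(hap) != 2L * length(sample_ids))
    stop(sprintf("write_panel: %d haplotype rows vs %d samples",
                 nrow(hap), length(sample_ids)))
  writeLines(sprintf("%s %d %s %s", markers$id, markers$pos,
                     markers$allele_a, markers$allele_b), markers_path)
  con <- file(bgl_path, "w")
  on.exit(close(con))
  writeLines(paste(c("I", "id", rep(sample_ids, each = 2L)), collapse = " "), con)
  for (j in seq_len(nrow(markers))) {
    chars <- if (startsWith(markers$id[j], "HLA_"))
      ifelse(hap[, j] == 1L, "P", "A")       # presence coded by character
    else
      ifelse(hap[, j] == 1L, markers$allele_b[j], markers$allele_a[j])
    writeLines(paste(c("M", markers$id[j], chars), collapse = " "), con)
  }
  invisible(c(markers = markers_path, bgl = bgl_path))
}

#' Read target SNP genotypes
#'
#' Accepts either the SNP2HLA dialect (markers + unphased-as-phased Beagle
#' file; HLA presence rows, if present, are ignored) or a VCF with GT
#' fields (needs the vcfR package; only biallelic SNP records are used,
#' others are skipped with a message). Missing genotypes are an error:
#' the pipeline expects pre-imputed, complete matrices.
#'
#' @param path phased/genotype file or VCF path.
#' @param markers_path markers file (dialect input only).
#' @return N x M dosage matrix over \{0,1,2\}, columns named by marker id.
#' @export
read_target_genotypes <- function(path, markers_path = NULL) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF targets requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    biallelic <- !grepl(",", fix[, "ALT"]) &
      nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
    n_skip <- sum(!biallelic)
    if (n_skip > 0L)
      message(sprintf("read_target_genotypes: skipped %d non-biallelic-SNP records", n_skip))
    gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
    if (anyNA(dos))
      stop("read_target_genotypes: missing genotypes in VCF; pre-impute first")
    d <- t(dos)
    storage.mode(d) <- "integer"
    return(d)
  }
  if (is.null(markers_path))
    stop("read_target_genotypes: markers_path required for dialect input")
  markers <- read_markers(markers_path)
  p <- read_bgl_phased(markers, path)
  haplotypes_to_dosage(p$snp, p$sample_ids)
}
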