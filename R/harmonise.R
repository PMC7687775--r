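#' @import data.table
NULL

#' Construct a reference panel object
#'
#' A reference panel holds the shared variant index (chromosome, position,
#' reference and alternative allele), per-variant alternative-allele
#' frequencies, an LD-block assignment for every variant (blocks are intended
#' to be recombination-hotspot-defined so that correlation across block
#' boundaries can be treated as zero), and, optionally, within-block LD
#' correlation matrices.
#'
#' @param variants a data.frame with columns `chr`, `pos` (1-based),
#'   `ref`, `alt`, `alt_freq` and `block`.
#' @param ld optional named list of per-block symmetric correlation matrices
#'   with unit diagonal; names are block labels, dimnames are variant keys.
#' @return an object of class `ref_panel`.
#' @export
reference_panel <- function(variants, ld = NULL) {
  v <- as.data.table(variants)
  need <- c("chr", "pos", "ref", "alt", "alt_freq", "block")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop_data("panel variant table lacks column(s): ", paste(miss, collapse = ", "))
  v[, `:=`(chr = as.character(chr), pos = as.integer(pos),
           ref = toupper(ref), alt = toupper(alt),
           block = as.character(block))]
  if (any(v$ref == v$alt)) stop_data("panel contains variants with ref == alt")
  if (any(v$alt_freq <= 0 | v$alt_freq >= 1))
    stop_data("panel alt_freq must lie strictly in (0, 1)")
  v[, key := variant_key(chr, pos, ref, alt)]
  if (anyDuplicated(v$key))
    stop_data("duplicate variant key(s) in panel: ",
              paste(utils::head(v$key[duplicated(v$key)], 3), collapse = ", "))
  if (!is.null(ld)) {
    bad <- setdiff(names(ld), unique(v$block))
    if (length(bad)) stop_data("LD matrices given for unknown block(s): ",
                               paste(bad, collapse = ", "))
    for (b in names(ld)) {
      m <- ld[[b]]
      if (max(abs(m)) > 1 + 1e-8) stop_data("|r| > 1 in LD matrix of block ", b)
    }
  }
  structure(list(variants = v[], ld = ld), class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference panel:", nrow(x$variants), "variants,",
      length(unique(x$variants$block)), "LD blocks,",
      if (is.null(x$ld)) "no LD matrices" else paste(length(x$ld), "LD matrices"),
      "\n")
  invisible(x)
}

# subset a panel to a logical/integer index, keeping LD matrices in step
panel_subset <- function(panel, idx) {
  v <- panel$variants[idx]
  ld <- panel$ld
  if (!is.null(ld)) {
    keep <- intersect(names(ld), unique(v$block))
    ld <- ld[keep]
    for (b in names(ld)) {
      keys <- v[block == b, key]
      ld[[b]] <- ld[[b]][keys, keys, drop = FALSE]
    }
    if (!length(ld)) ld <- NULL
  }
  reference_panel(v[, !"key"], ld)
}

#' Read a reference panel from plain-text files
#'
#' @param variant_file TSV with columns `chr`, `pos`, `ref`, `alt`,
#'   `alt_freq` and either a `block` column or none (then `block_file`
#'   is required).
#' @param block_file optional BED file (0-based, half-open) of LD-block
#'   intervals; the interval rank (per file order) becomes the block label.
#' @param ld_file optional long-format TSV with columns `block`, `key_i`,
#'   `key_j`, `r` giving within-block correlations (diagonal implied).
#' @return a `ref_panel`.
#' @export
load_reference_panel <- function(variant_file, block_file = NULL, ld_file = NULL) {
  if (!file.exists(variant_file)) stop_data("cannot read panel file: ", variant_file)
  v <- fread(variant_file)
  if (!"block" %in% names(v)) {
    if (is.null(block_file)) stop_data("panel has no 'block' column and no block_file given")
    bed <- read_bed(block_file)
    v[, block := NA_character_]
    for (i in seq_len(nrow(bed))) {
      hit <- v$chr == bed$chr[i] & v$pos > bed$start[i] & v$pos <= bed$end[i]
      v[hit, block := sprintf("b%04d", i)]
    }
    if (anyNA(v$block)) stop_data("some panel variants fall outside all block intervals")
  }
  ld <- NULL
  if (!is.null(ld_file)) {
    lt <- fread(ld_file)
    keys <- variant_key(v$chr, v$pos, v$ref, v$alt)
    ld <- lapply(split(lt, lt$block), function(d) {
      bk <- keys[variant_key(v$chr, v$pos, v$ref, v$alt) %in% c(d$key_i, d$key_j)]
      bk <- unique(c(d$key_i, d$key_j))
      m <- diag(length(bk)); dimnames(m) <- list(bk, bk)
      m[cbind(match(d$key_i, bk), match(d$key_j, bk))] <- d$r
      m[cbind(match(d$key_j, bk), match(d$key_i, bk))] <- d$r
      m
    })
  }
  reference_panel(v, ld)
}

#' Read genomic intervals from a BED file
#'
#' BED convention: 0-based, half-open `[start, end)`; a 1-based position
#' `pos` lies inside iff `start < pos <= end`.
#' @param path BED file with at least 3 columns.
#' @return data.table with columns `chr`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_data("cannot read BED file: ", path)
  b <- fread(path, header = FALSE)
  if (ncol(b) < 3) stop_data("BED file needs >= 3 columns: ", path)
  setnames(b, 1:3, c("chr", "start", "end"))
  b[, .(chr = as.character(chr), start = as.numeric(start), end = as.numeric(end))]
}

#' Default MHC exclusion mask (GRCh37 chr6:20-40Mb), in BED convention
#' @return data.table with columns `chr`, `start`, `end`.
#' @export
mhc_mask <- function() {
  data.table(chr = "6", start = 20e6, end = 40e6)
}

#' Load GWAS summary statistics from a delimited text file
#'
#' Rows with missing or non-finite `beta` or `se`, or `se <= 0`, are dropped
#' with a message. By default only bi-allelic SNPs (single-base A/C/G/T
#' alleles) are retained; indels and multi-base alleles are dropped unless
#' `keep_indels = TRUE`.
#'
#' @param path tab- or comma-separated file with at least chromosome,
#'   position, the two alleles, the effect estimate and its standard error.
#' @param column_map named list mapping internal names `chr`, `pos`, `ref`,
#'   `alt`, `beta`, `se` (optionally `n_cases`, `n_controls`) to the file's
#'   column names. Defaults to the internal names themselves.
#' @param trait_id label for the study; defaults to the file name.
#' @param keep_indels retain bi-allelic indels (multi-base alleles)?
#' @return an object of class `sumstats`.
#' @export
load_summary_stats <- function(path, column_map = NULL, trait_id = NULL,
                               keep_indels = FALSE) {
  if (!file.exists(path)) stop_data("cannot read summary-statistic file: ", path)
  raw <- fread(path)
  cm <- utils::modifyList(
    list(chr = "chr", pos = "pos", ref = "ref", alt = "alt",
         beta = "beta", se = "se"),
    as.list(column_map %||% list()))
  need <- c("chr", "pos", "ref", "alt", "beta", "se")
  for (f in need)
    if (!cm[[f]] %in% names(raw))
      stop_data("required column '", cm[[f]], "' (", f, ") absent from ", path)
  d <- data.table(chr = as.character(raw[[cm$chr]]),
                  pos = as.integer(raw[[cm$pos]]),
                  ref = toupper(as.character(raw[[cm$ref]])),
                  alt = toupper(as.character(raw[[cm$alt]])),
                  beta = as.numeric(raw[[cm$beta]]),
                  se = as.numeric(raw[[cm$se]]))
  nc <- if (!is.null(cm$n_cases) && cm$n_cases %in% names(raw))
    raw[[cm$n_cases]][1] else NA_integer_
  nco <- if (!is.null(cm$n_controls) && cm$n_controls %in% names(raw))
    raw[[cm$n_controls]][1] else NA_integer_
  sumstats(d, trait_id = trait_id %||% basename(path),
           n_cases = nc, n_controls = nco,
           provenance = path, keep_indels = keep_indels)
}

#' Construct a summary-statistics object from a data.frame
#'
#' @param snps data.frame with columns `chr`, `pos`, `ref`, `alt`, `beta`, `se`.
#' @param trait_id study label.
#' @param n_cases,n_controls optional sample sizes.
#' @param provenance free-text origin note.
#' @param keep_indels see [load_summary_stats()].
#' @return an object of class `sumstats`: a list with elements `trait_id`,
#'   `snps` (data.table keyed by variant), `n_cases`, `n_controls`,
#'   `provenance` and an `aligned` flag.
#' @export
sumstats <- function(snps, trait_id, n_cases = NA, n_controls = NA,
                     provenance = "", keep_indels = FALSE) {
  d <- as.data.table(snps)
  d[, `:=`(chr = as.character(chr), pos = as.integer(pos),
           ref = toupper(ref), alt = toupper(alt),
           beta = as.numeric(beta), se = as.numeric(se))]
  n0 <- nrow(d)
  bad <- !is.finite(d$beta) | !is.finite(d$se) | d$se <= 0
  if (any(bad)) {
    message(trait_id, ": dropped ", sum(bad),
            " row(s) with missing/non-finite beta or se, or se <= 0")
    d <- d[!bad]
  }
  snp_ok <- d$ref %chin% c("A", "C", "G", "T") & d$alt %chin% c("A", "C", "G", "T")
  if (!keep_indels && any(!snp_ok)) {
    message(trait_id, ": dropped ", sum(!snp_ok), " non-SNP (indel/multi-base) row(s)")
    d <- d[snp_ok]
  }
  if (any(d$ref == d$alt)) stop_data(trait_id, ": variant with ref == alt")
  d[, key := variant_key(chr, pos, ref, alt)]
  if (anyDuplicated(d$key))
    stop_data(trait_id, ": duplicate variant key(s): ",
              paste(utils::head(unique(d$key[duplicated(d$key)]), 3), collapse = ", "))
  structure(list(trait_id = trait_id, snps = d[], n_cases = n_cases,
                 n_controls = n_controls, provenance = provenance,
                 aligned = FALSE),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat("Summary statistics for '", x$trait_id, "': ", nrow(x$snps), " variants",
      if (isTRUE(x$aligned)) " (panel-aligned)", "\n", sep = "")
  invisible(x)
}

is_palindromic <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Align a study to a reference panel
#'
#' Harmonises effect estimates to be with respect to the panel's alternative
#' allele: where the study reports the effect for the panel's reference
#' allele (alleles swapped), the sign of `beta` is flipped. Strand-ambiguous
#' palindromic variants (A/T, C/G) are always dropped, as are variants whose
#' alleles match the panel neither directly nor swapped; no strand flipping
#' is attempted. Panel variants absent from the study are retained with
#' missing `beta`/`se` (their treatment is deferred to projection).
#'
#' The operation is idempotent: aligning an already-aligned study is a no-op.
#'
#' @param ss a `sumstats` object.
#' @param panel a `ref_panel`.
#' @return a `sumstats` object whose `snps` table has exactly one row per
#'   panel variant, in panel order, with `aligned = TRUE`.
#' @export
align_to_panel <- function(ss, panel) {
  stopifnot(inherits(ss, "sumstats"), inherits(panel, "ref_panel"))
  pv <- panel$variants
  d <- copy(ss$snps)
  pal <- is_palindromic(d$ref, d$alt)
  if (any(pal)) {
    if (!isTRUE(ss$aligned))
      message(ss$trait_id, ": dropped ", sum(pal), " palindromic variant(s)")
    d <- d[!pal]
  }
  direct <- match(pv$key, d$key)
  swapped <- match(variant_key(pv$chr, pv$pos, pv$alt, pv$ref), d$key)
  swapped[!is.na(direct)] <- NA  # direct match wins (cannot co-occur anyway)
  beta <- ifelse(!is.na(direct), d$beta[direct],
                 ifelse(!is.na(swapped), -d$beta[swapped], NA_real_))
  se <- ifelse(!is.na(direct), d$se[direct],
               ifelse(!is.na(swapped), d$se[swapped], NA_real_))
  if (all(is.na(beta)))
    stop_data(ss$trait_id, ": no variants overlap the reference panel")
  out <- data.table(chr = pv$chr, pos = pv$pos, ref = pv$ref, alt = pv$alt,
                    beta = beta, se = se)
  out[, key := pv$key]
  structure(list(trait_id = ss$trait_id, snps = out, n_cases = ss$n_cases,
                 n_controls = ss$n_controls, provenance = ss$provenance,
                 aligned = TRUE),
            class = "sumstats")
}

#' Filter a reference panel by MAF and exclusion intervals
#'
#' Keeps variants with minor allele frequency strictly greater than
#' `maf_min` and lying outside all exclusion intervals (BED convention,
#' 0-based half-open); block structure and LD matrices are subset in step.
#'
#' @param panel a `ref_panel`.
#' @param maf_min minimum minor allele frequency, in `[0, 0.5)`.
#' @param exclude data.frame of intervals with columns `chr`, `start`,
#'   `end`, e.g. [mhc_mask()]; or `NULL` for none.
#' @return the filtered `ref_panel`.
#' @export
filter_panel <- function(panel, maf_min = 0.01, exclude = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5)
    stop_data("maf_min must lie in [0, 0.5)")
  v <- panel$variants
  maf <- pmin(v$alt_freq, 1 - v$alt_freq)
  keep <- maf > maf_min
  if (!is.null(exclude)) {
    ex <- as.data.table(exclude)
    for (i in seq_len(nrow(ex))) {
      keep <- keep & !(v$chr == as.character(ex$chr[i]) &
                         v$pos > ex$start[i] & v$pos <= ex$end[i])
    }
  }
  dropped <- sum(!keep)
  if (dropped) message("filter_panel: removed ", dropped, " variant(s)")
  panel_subset(panel, keep)
}

#' Shared variant index across aligned studies
#'
#' Returns, in panel order, the variant keys with a non-missing effect
#' estimate in every study.
#'
#' @param studies list of panel-aligned `sumstats` objects on the same panel.
#' @return character vector of variant keys.
#' @export
intersect_studies <- function(studies) {
  if (length(studies) < 2) stop_data("need at least 2 studies to intersect")
  keys <- studies[[1]]$snps$key
  for (s in studies) {
    if (!isTRUE(s$aligned)) stop_data("study '", s$trait_id, "' is not panel-aligned")
    if (!identical(s$snps$key, keys))
      stop_data("studies are not aligned to the same panel index")
  }
  present <- Reduce(`&`, lapply(studies, function(s) !is.na(s$snps$beta)))
  if (!any(present)) stop_data("no variant is present in all studies")
  keys[present]
}
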