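# Reading GWAS summary statistics and LD references, and harmonizing
# exposure/outcome tables onto a common effect-allele orientation.

.CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
.REQUIRED_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P")

#' Construct a per-trait GWAS summary table
#'
#' A summary table holds one row per SNP for a single trait: identifier,
#' location, alleles, effect-allele frequency, effect size (per-SD units for a
#' quantitative exposure, log-odds for a binary outcome), standard error,
#' p-value and sample size.
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval` and optionally `n`.
#' @param trait_id Trait label, e.g. a metabolite identifier.
#' @param trait_role `"exposure"` or `"outcome"`.
#' @return A `summary_table` (a data.frame with `trait_id`/`trait_role`
#'   attributes).
#' @export
summary_table <- function(df, trait_id, trait_role = c("exposure", "outcome")) {
  trait_role <- match.arg(trait_role)
  needed <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pval")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_config(sprintf("summary table for '%s' is missing column(s): %s",
                        trait_id, paste(missing_cols, collapse = ", ")))
  }
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[, c(needed, "n")]
  dup <- df$snp_id[duplicated(df$snp_id)]
  if (length(dup) > 0) {
    stop_input(sprintf("duplicated snp_id in table '%s': %s",
                       trait_id, paste(unique(dup), collapse = ", ")))
  }
  bad_se <- !is.na(df$se) & df$se <= 0
  if (any(bad_se)) stop_input("se must be > 0 for all records")
  bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  if (any(bad_eaf)) stop_input("eaf must lie in [0, 1] when present")
  same <- df$effect_allele == df$other_allele
  if (any(same)) {
    stop_input(sprintf("effect and other allele identical for: %s",
                       paste(df$snp_id[same], collapse = ", ")))
  }
  rownames(df) <- NULL
  structure(df, trait_id = trait_id, trait_role = trait_role,
            class = c("summary_table", "data.frame"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table '%s' (%s): %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_role"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

trait_id <- function(x) attr(x, "trait_id")
trait_role <- function(x) attr(x, "trait_role")

#' Read a column-name mapping file
#'
#' One `canonical: actual` pair per line, mapping the canonical column names
#' (`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`) to the names used by a
#' particular summary-statistics dialect.
#'
#' @param path Path to the mapping file.
#' @return Named character vector (canonical name -> file column name).
#' @export
read_column_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop_config(sprintf("malformed column-map line: '%s'", lines[bad][1]))
  map <- trimws(vapply(parts, `[`, "", 2L))
  names(map) <- trimws(toupper(vapply(parts, `[`, "", 1L)))
  map
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads tab- or comma-separated summary statistics with a header row into a
#' [summary_table()]. Rows whose effect size, standard error or p-value cannot
#' be parsed (or violate their domains: `se > 0`, `p` in (0, 1], `eaf` in
#' \[0, 1\]), and rows carrying indel or multi-allelic codes, are dropped and
#' counted; the counts are attached as the `"n_dropped"` attribute and
#' reported via [message()].
#'
#' @param path Path to the file. The field separator is sniffed from the
#'   header (tab beats comma).
#' @param trait_id,trait_role Trait label and role (see [summary_table()]).
#' @param column_map Optional named character vector (or path to a
#'   `key: value` file, see [read_column_map()]) translating canonical column
#'   names `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` to the file's own
#'   header names. By default the canonical names are expected verbatim.
#' @return A [summary_table()].
#' @export
read_summary_stats <- function(path, trait_id, trait_role = c("exposure", "outcome"),
                               column_map = NULL) {
  trait_role <- match.arg(trait_role)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  if (is.character(column_map) && length(column_map) == 1L && is.null(names(column_map))) {
    column_map <- read_column_map(column_map)
  }
  map <- stats::setNames(.CANONICAL_COLS, .CANONICAL_COLS)
  if (!is.null(column_map)) map[toupper(names(column_map))] <- unname(column_map)
  missing_req <- .REQUIRED_COLS[!map[.REQUIRED_COLS] %in% names(raw)]
  if (length(missing_req) > 0) {
    stop_config(sprintf("missing required column(s) in %s: %s",
                        path, paste(map[missing_req], collapse = ", ")))
  }
  get_col <- function(canon, default = NA_character_) {
    if (map[[canon]] %in% names(raw)) raw[[map[[canon]]]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    snp_id = get_col("SNP"),
    chrom = as.character(get_col("CHR")),
    pos = num(get_col("POS")),
    effect_allele = toupper(get_col("EA")),
    other_allele = toupper(get_col("OA")),
    eaf = num(get_col("EAF")),
    beta = num(get_col("BETA")),
    se = num(get_col("SE")),
    pval = num(get_col("P")),
    n = num(get_col("N")),
    stringsAsFactors = FALSE
  )
  drops <- c(unparseable = 0L, invalid_allele = 0L)
  ok_num <- is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
  drops["unparseable"] <- sum(!ok_num)
  # Biallelic SNPs only: single-base A/C/G/T alleles, rejected otherwise.
  ok_allele <- df$effect_allele %in% names(.COMPLEMENT) &
    df$other_allele %in% names(.COMPLEMENT) &
    df$effect_allele != df$other_allele
  drops["invalid_allele"] <- sum(ok_allele[ok_num] == FALSE)
  df <- df[ok_num & ok_allele, , drop = FALSE]
  if (nrow(df) == 0) stop_input(sprintf("no usable records in %s", path))
  if (sum(drops) > 0) {
    message(sprintf("read_summary_stats(%s): dropped %d row(s) (%d unparseable/out-of-domain, %d indel/multi-allelic)",
                    basename(path), sum(drops), drops["unparseable"], drops["invalid_allele"]))
  }
  out <- summary_table(df, trait_id = trait_id, trait_role = trait_role)
  attr(out, "n_dropped") <- drops
  out
}

#' Write a summary table to tab-separated text
#'
#' Uses the canonical header `SNP CHR POS EA OA EAF BETA SE P N`, the dialect
#' read back by [read_summary_stats()].
#'
#' @param table A [summary_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  out <- data.frame(SNP = table$snp_id, CHR = table$chrom, POS = table$pos,
                    EA = table$effect_allele, OA = table$other_allele,
                    EAF = table$eaf, BETA = table$beta, SE = table$se,
                    P = table$pval, N = table$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an LD reference panel
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param r2 Square matrix of pairwise squared correlations (unit diagonal,
#'   symmetric, entries in \[0, 1\]).
#' @param chrom,pos Optional per-SNP coordinates.
#' @return An `ld_panel` object.
#' @export
ld_panel <- function(snp_ids, r2, chrom = NULL, pos = NULL) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids)) {
    stop_input("r2 matrix dimensions must match snp_ids")
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop_input("r2 values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop_input("r2 matrix must be symmetric")
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, chrom = chrom, pos = pos, r2 = r2),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  off <- x$r2[upper.tri(x$r2)]
  cat(sprintf("LD panel: %d SNPs, %d non-zero off-diagonal r2 pairs\n",
              length(x$snp_ids), sum(off > 0)))
  invisible(x)
}

#' Pairwise r-squared lookup
#'
#' @param panel An [ld_panel()].
#' @param a,b SNP identifiers.
#' @return r² in \[0, 1\], or `NA` when either SNP is absent from the panel.
#' @export
panel_r2 <- function(panel, a, b) {
  if (!(a %in% panel$snp_ids) || !(b %in% panel$snp_ids)) return(NA_real_)
  panel$r2[a, b]
}

#' Read an LD reference from plain text
#'
#' Two dialects: `"pairwise"` lists `SNP_A SNP_B R2` (one row per correlated
#' pair; absent pairs default to r² = 0), matching the pairwise LD reports of
#' standard genotype toolkits. `"genotype"` is a SNP-by-sample allele-dosage
#' matrix whose first three columns are `SNP CHR POS`; r² is computed as the
#' squared sample correlation of dosages.
#'
#' @param path Path to the file (tab- or comma-separated, header row).
#' @param format `"pairwise"` or `"genotype"`.
#' @return An [ld_panel()].
#' @export
read_ld_panel <- function(path, format = c("pairwise", "genotype")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "pairwise") {
    names(raw) <- toupper(names(raw))
    need <- c("SNP_A", "SNP_B", "R2")
    if (!all(need %in% names(raw))) {
      stop_config(sprintf("pairwise LD file must have columns %s", paste(need, collapse = ", ")))
    }
    if (any(!is.finite(raw$R2)) || any(raw$R2 < 0) || any(raw$R2 > 1)) {
      stop_input("r2 values must lie in [0, 1]")
    }
    ids <- sort(unique(c(raw$SNP_A, raw$SNP_B)))
    r2 <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_len(nrow(raw))) {
      r2[raw$SNP_A[i], raw$SNP_B[i]] <- raw$R2[i]
      r2[raw$SNP_B[i], raw$SNP_A[i]] <- raw$R2[i]
    }
    diag(r2) <- 1
    ld_panel(ids, r2)
  } else {
    if (ncol(raw) < 4L) stop_config("genotype LD file needs SNP, CHR, POS plus dosage columns")
    ids <- as.character(raw[[1]])
    dos <- as.matrix(raw[, -(1:3), drop = FALSE])
    storage.mode(dos) <- "double"
    cc <- suppressWarnings(stats::cor(t(dos)))
    cc[!is.finite(cc)] <- 0  # monomorphic rows have undefined correlation
    r2 <- cc^2
    r2[r2 > 1] <- 1
    diag(r2) <- 1
    ld_panel(ids, r2, chrom = as.character(raw[[2]]), pos = as.numeric(raw[[3]]))
  }
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table onto the exposure's effect-allele orientation over
#' the shared SNPs. When the outcome's alleles are recorded swapped (or on the
#' opposite strand), the outcome effect is negated and its effect-allele
#' frequency replaced by its complement, with `flipped = TRUE`. Palindromic
#' SNPs (A/T, G/C) cannot be strand-resolved from labels: under
#' `palindromic_policy = "drop"` they are removed; under `"infer"` they are
#' aligned by comparing effect-allele frequencies against 0.5 (same side:
#' orientation kept; opposite sides: flipped) and dropped as ambiguous when
#' `min(eaf, 1 - eaf) > maf_infer_threshold` in either study or when either
#' frequency is missing. SNP pairs whose alleles cannot be reconciled under
#' any strand/swap combination are dropped and logged.
#'
#' @param exposure,outcome [summary_table()]s; the exposure provides the
#'   per-SNP effects \eqn{\gamma_j} (with SE \eqn{\sigma_{Xj}}), the outcome
#'   \eqn{\Gamma_j} (with SE \eqn{\sigma_{Yj}}).
#' @param palindromic_policy `"infer"` (default) or `"drop"`.
#' @param maf_infer_threshold Ambiguity cutoff for frequency inference
#'   (default 0.42).
#' @return A `harmonized_set`: a data.frame with columns `snp_id, chrom, pos,
#'   effect_allele, other_allele, gamma, sigma_x, Gamma, sigma_y,
#'   eaf_exposure, eaf_outcome, pval_exposure, palindromic, flipped`, plus a
#'   `drops` attribute recording removals by reason.
#' @export
harmonize <- function(exposure, outcome, palindromic_policy = c("infer", "drop"),
                      maf_infer_threshold = 0.42) {
  palindromic_policy <- match.arg(palindromic_policy)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) stop_input("both tables must be non-empty")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) stop_analysis("no shared instruments")
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  n <- length(shared)
  keep <- rep(TRUE, n)
  flip <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  csame <- flip_strand(ou$effect_allele) == ex$effect_allele &
    flip_strand(ou$other_allele) == ex$other_allele
  cswap <- flip_strand(ou$effect_allele) == ex$other_allele &
    flip_strand(ou$other_allele) == ex$effect_allele

  resolvable <- same | swap | csame | cswap
  keep[!resolvable] <- FALSE
  reason[!resolvable] <- "non_resolvable"

  np <- resolvable & !pal
  flip[np] <- swap[np] | cswap[np]

  pp <- resolvable & pal
  if (any(pp)) {
    if (palindromic_policy == "drop") {
      keep[pp] <- FALSE
      reason[pp] <- "palindromic"
    } else {
      f_ex <- ex$eaf
      f_ou <- ou$eaf
      no_freq <- pp & (is.na(f_ex) | is.na(f_ou))
      keep[no_freq] <- FALSE
      reason[no_freq] <- "palindromic_missing_eaf"
      amb <- pp & !no_freq &
        (pmin(f_ex, 1 - f_ex) > maf_infer_threshold |
           pmin(f_ou, 1 - f_ou) > maf_infer_threshold)
      keep[amb] <- FALSE
      reason[amb] <- "palindromic_ambiguous"
      inf <- pp & keep
      # Same side of 0.5: labelled effect alleles agree; opposite: strand flip.
      flip[inf] <- (f_ex[inf] < 0.5) != (f_ou[inf] < 0.5)
    }
  }

  Gamma <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  h <- data.frame(
    snp_id = shared,
    chrom = ex$chrom,
    pos = ex$pos,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    gamma = ex$beta,
    sigma_x = ex$se,
    Gamma = Gamma,
    sigma_y = ou$se,
    eaf_exposure = ex$eaf,
    eaf_outcome = eaf_out,
    pval_exposure = ex$pval,
    palindromic = pal,
    flipped = flip,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(h) <- NULL
  if (nrow(h) == 0) stop_analysis("no shared instruments after allele harmonization")

  drops <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                      stringsAsFactors = FALSE)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("harmonize(%s ~ %s): dropped %d SNP(s) (%s)",
                    trait_id(exposure) %||% "exposure", trait_id(outcome) %||% "outcome",
                    n_dropped, paste(sort(unique(drops$reason)), collapse = ", ")))
  }
  structure(h,
            exposure_id = trait_id(exposure), outcome_id = trait_id(outcome),
            drops = drops,
            counts = c(input = length(shared), harmonized = nrow(h),
                       dropped = n_dropped),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set %s ~ %s: %d SNPs (%d flipped, %d palindromic kept)\n",
              attr(x, "exposure_id") %||% "?", attr(x, "outcome_id") %||% "?",
              nrow(x), sum(x$flipped), sum(x$palindromic)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# Internal: build a harmonized_set directly from aligned vectors (used by the
# simulator and by tests, bypassing file IO).
make_harmonized <- function(gamma, sigma_x, Gamma, sigma_y,
                            snp_id = sprintf("rs%04d", seq_along(gamma)),
                            exposure_id = "exposure", outcome_id = "outcome",
                            chrom = "1", pos = seq_along(gamma)) {
  stopifnot(length(gamma) == length(Gamma),
            length(sigma_x) %in% c(1L, length(gamma)),
            length(sigma_y) %in% c(1L, length(gamma)))
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) stop_input("standard errors must be > 0")
  h <- data.frame(snp_id = snp_id, chrom = rep_len(as.character(chrom), length(gamma)),
                  pos = rep_len(pos, length(gamma)),
                  effect_allele = "A", other_allele = "G",
                  gamma = gamma, sigma_x = rep_len(sigma_x, length(gamma)),
                  Gamma = Gamma, sigma_y = rep_len(sigma_y, length(gamma)),
                  eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                  pval_exposure = NA_real_,
                  palindromic = FALSE, flipped = FALSE,
                  stringsAsFactors = FALSE)
  structure(h, exposure_id = exposure_id, outcome_id = outcome_id,
            drops = data.frame(snp_id = character(), reason = character()),
            counts = c(input = nrow(h), harmonized = nrow(h), dropped = 0L),
            class = c("harmonized_set", "data.frame"))
}
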