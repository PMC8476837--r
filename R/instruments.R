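# Instrument selection: p-value threshold, greedy LD clumping,
# cross-exposure restriction, exclusion list, and the per-exposure
# instrument-count filter, with a per-stage audit trail.

.TRACE_STAGES <- c("initial", "after_pvalue", "after_clump",
                   "after_restriction", "after_exclusion_list", "final")

new_instrument_set <- function(exposure_id, snp_ids, provenance, trace) {
  structure(list(exposure_id = exposure_id,
                 snp_ids = as.character(snp_ids),
                 provenance = provenance,
                 trace = trace),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set '%s': %d SNP(s)\n", x$exposure_id, length(x$snp_ids)))
  tr <- x$trace[!is.na(x$trace)]
  cat("  trace:", paste(sprintf("%s=%d", names(tr), tr), collapse = " -> "), "\n")
  invisible(x)
}

#' Per-stage filter counts for an instrument set
#'
#' @param x An `instrument_set`.
#' @return Named integer vector over the stages `initial, after_pvalue,
#'   after_clump, after_restriction, after_exclusion_list, final` (`NA` for
#'   stages not yet applied). Counts are non-increasing across applied stages.
#' @export
filter_trace <- function(x) {
  tr <- x$trace
  tr["final"] <- length(x$snp_ids)
  tr
}

mark_removed <- function(set, removed, stage) {
  if (length(removed) > 0) {
    idx <- match(removed, set$provenance$snp_id)
    set$provenance$removed_at[idx] <- stage
  }
  set$snp_ids <- setdiff(set$snp_ids, removed)
  set$trace[stage] <- length(set$snp_ids)
  set
}

#' Preliminary instrument selection by association p-value
#'
#' Retains exactly the SNPs whose exposure p-value is strictly below the
#' threshold (default 1e-5, the loose genome-wide screen commonly used to
#' select metabolite instruments).
#'
#' @param table Exposure [summary_table()].
#' @param threshold Selection p-value threshold; strict `<`.
#' @return An `instrument_set` with provenance and a [filter_trace()].
#' @export
select_by_pvalue <- function(table, threshold = 1e-5) {
  if (!identical(trait_role(table), "exposure")) {
    stop_input("select_by_pvalue expects a table with trait_role = 'exposure'")
  }
  keep <- table$pval < threshold
  prov <- data.frame(snp_id = table$snp_id,
                     removed_at = ifelse(keep, NA_character_, "after_pvalue"),
                     stringsAsFactors = FALSE)
  trace <- stats::setNames(rep(NA_integer_, length(.TRACE_STAGES)), .TRACE_STAGES)
  trace["initial"] <- nrow(table)
  trace["after_pvalue"] <- sum(keep)
  new_instrument_set(trait_id(table), table$snp_id[keep], prov, trace)
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the unremoved candidate with the smallest exposure
#' p-value as an index SNP and removes every other candidate on the same
#' chromosome within `window_kb` of it whose r² with the index exceeds
#' `r2_cutoff`. Surviving index SNPs are mutually independent at the cutoff
#' within the window. Ties on p-value are broken by `(chrom, pos, snp_id)`
#' ascending so the output never depends on input order. Candidates absent
#' from the panel are treated as independent and logged.
#'
#' @param candidates `instrument_set` from [select_by_pvalue()].
#' @param exposure The exposure [summary_table()] (for p-values and positions).
#' @param panel An [ld_panel()], or `NULL` to treat all SNPs as independent.
#' @param r2_cutoff LD pruning threshold (default 0.001); removal requires
#'   strict `r2 > r2_cutoff`.
#' @param window_kb Window in kilobases (default 10000); inclusive distance
#'   `|pos_i - pos_j| <= window_kb * 1000`, same chromosome only.
#' @return The clumped `instrument_set`.
#' @export
ld_clump <- function(candidates, exposure, panel, r2_cutoff = 0.001, window_kb = 10000) {
  ids <- candidates$snp_ids
  if (length(ids) <= 1) {
    candidates$trace["after_clump"] <- length(ids)
    return(candidates)
  }
  rows <- exposure[match(ids, exposure$snp_id), , drop = FALSE]
  if (anyNA(rows$snp_id)) {
    stop_input("clump candidates missing from exposure table")
  }
  if (!is.null(panel)) {
    absent <- setdiff(ids, panel$snp_ids)
    if (length(absent) > 0) {
      message(sprintf("ld_clump(%s): %d candidate(s) absent from LD panel, treated as independent",
                      candidates$exposure_id, length(absent)))
    }
  }
  ord <- order(rows$pval, rows$chrom, rows$pos, rows$snp_id)
  id_o <- rows$snp_id[ord]
  chr_o <- rows$chrom[ord]
  pos_o <- rows$pos[ord]
  window_bp <- window_kb * 1000
  n <- length(id_o)
  active <- rep(TRUE, n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    if (!active[i]) next
    kept[i] <- TRUE
    for (j in seq_len(n)) {
      if (j == i || !active[j]) next
      if (chr_o[j] != chr_o[i]) next
      if (abs(pos_o[j] - pos_o[i]) > window_bp) next
      r2 <- if (is.null(panel)) 0 else panel_r2(panel, id_o[i], id_o[j])
      if (is.na(r2)) r2 <- 0  # absent from panel: assumed independent
      if (r2 > r2_cutoff) active[j] <- FALSE
    }
  }
  survivors <- id_o[kept]
  # Preserve the original candidate ordering in the result.
  survivors <- ids[ids %in% survivors]
  mark_removed(candidates, setdiff(ids, survivors), "after_clump")
}

#' Cross-exposure instrument restriction
#'
#' Removes, from every exposure's instrument set, any SNP whose exposure
#' p-value falls below `association_threshold` in at least `min_share`
#' exposure tables. Such SNPs regulate several exposures at once and threaten
#' the exclusion-restriction assumption.
#'
#' @param per_exposure Named list of `instrument_set`s, keyed by exposure id.
#' @param all_exposures Named list of exposure [summary_table()]s used to
#'   count associations (typically the full panel, not just those with
#'   instrument sets).
#' @param association_threshold P-value defining "associated"; should match
#'   the selection threshold (default 1e-5).
#' @param min_share Minimum number of exposures sharing a SNP for removal
#'   (default 2).
#' @return The updated named list of `instrument_set`s.
#' @export
restrict_cross_exposure <- function(per_exposure, all_exposures,
                                    association_threshold = 1e-5, min_share = 2L) {
  sig_snps <- unlist(lapply(all_exposures, function(tab) {
    unique(tab$snp_id[!is.na(tab$pval) & tab$pval < association_threshold])
  }), use.names = FALSE)
  counts <- table(sig_snps)
  shared <- names(counts)[counts >= min_share]
  lapply(per_exposure, function(set) {
    mark_removed(set, intersect(set$snp_ids, shared), "after_restriction")
  })
}

#' Remove listed SNPs from an instrument set
#'
#' Set difference against an exclusion list of SNP identifiers (e.g. variants
#' known to associate with the outcome disease or its risk factors).
#'
#' @param instruments An `instrument_set`.
#' @param exclusion Character vector of snp_ids (see [read_exclusion_list()]).
#' @return The filtered `instrument_set`.
#' @export
apply_exclusion_list <- function(instruments, exclusion) {
  mark_removed(instruments, intersect(instruments$snp_ids, exclusion),
               "after_exclusion_list")
}

#' Read a SNP exclusion list
#'
#' Plain text, one snp_id per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the list.
#' @return Character vector of snp_ids.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Drop exposures with too few or too many instruments
#'
#' Exposures whose instrument count falls outside `[min_iv, max_iv]`
#' (boundaries inclusive) are removed entirely; too few instruments give
#' unstable estimates and very many suggest a poorly specified exposure.
#'
#' @param per_exposure Named list of `instrument_set`s.
#' @param min_iv,max_iv Inclusive bounds (defaults 3 and 100).
#' @return The surviving named list, with a `"removed"` attribute
#'   (data.frame of exposure_id, n_iv, reason).
#' @export
filter_iv_count <- function(per_exposure, min_iv = 3L, max_iv = 100L) {
  if (!is_count(min_iv, min = 1)) stop_input("min_iv must be a count >= 1")
  n_iv <- vapply(per_exposure, function(s) length(s$snp_ids), 1L)
  keep <- n_iv >= min_iv & n_iv <= max_iv
  removed <- data.frame(exposure_id = names(per_exposure)[!keep],
                        n_iv = unname(n_iv[!keep]),
                        reason = ifelse(n_iv[!keep] < min_iv,
                                        sprintf("fewer than %d instruments", min_iv),
                                        sprintf("more than %d instruments", max_iv)),
                        stringsAsFactors = FALSE)
  out <- per_exposure[keep]
  out <- lapply(out, function(s) { s$trace["final"] <- length(s$snp_ids); s })
  attr(out, "removed") <- removed
  out
}
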