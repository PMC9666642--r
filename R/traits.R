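#' Fixation report for trait-associated markers
#'
#' For each trait marker and sample group, classifies the marker as
#' `fixed_ref` (every non-missing AF at or below `tol`), `fixed_alt`
#' (every AF at or above `100 - tol`), `segregating`, or `missing` (no
#' data in the group). The summary counts markers fixed for the reference
#' allele in every group simultaneously — the pattern reported for a
#' third of the varroa-resistance-associated markers, which segregate in
#' none of the surveyed populations.
#'
#' @param af An AF matrix (percent).
#' @param sheet A `sample_sheet` covering its rows.
#' @param markers Trait marker ids (e.g. `marker_subset(panel, "trait")`).
#' @param group_by Sheet column defining the groups.
#' @param tol Fixation tolerance in percentage points (default 0: strict).
#' @return A `fixation_report` list: `status` (markers x groups character
#'   matrix), `mean_af` (markers x groups percent means),
#'   `n_fixed_ref_all_groups`.
#' @export
fixation_report <- function(af, sheet, markers, group_by = "subspecies",
                            tol = 0) {
  stopifnot(is.matrix(af), length(markers) > 0L, tol >= 0, tol < 50)
  missing_m <- setdiff(markers, colnames(af))
  if (length(missing_m) > 0L) {
    stop("marker(s) absent from AF matrix: ", paste(missing_m, collapse = ", "))
  }
  ids <- rownames(af)
  grp <- sheet[[group_by]][match(ids, sheet$sample_id)]
  groups <- unique(grp[!is.na(grp)])
  if (length(groups) == 0L) stop("no non-missing groups in column ", group_by)
  status <- matrix(NA_character_, length(markers), length(groups),
                   dimnames = list(markers, groups))
  mean_af <- matrix(NA_real_, length(markers), length(groups),
                    dimnames = list(markers, groups))
  for (g in groups) {
    rows <- af[which(grp %in% g), markers, drop = FALSE]
    if (nrow(rows) == 0L) stop("group with zero samples: ", g)
    for (mk in markers) {
      v <- rows[, mk]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        status[mk, g] <- "missing"
      } else {
        mean_af[mk, g] <- mean(v)
        status[mk, g] <- if (all(v <= tol)) "fixed_ref"
        else if (all(v >= 100 - tol)) "fixed_alt"
        else "segregating"
      }
    }
  }
  n_all <- sum(apply(status == "fixed_ref", 1L, all))
  structure(list(status = status, mean_af = mean_af,
                 n_fixed_ref_all_groups = n_all, tol = tol),
            class = "fixation_report")
}

#' @export
print.fixation_report <- function(x, ...) {
  cat(sprintf("fixation report: %d trait markers x %d groups (tol = %g pp)\n",
              nrow(x$status), ncol(x$status), x$tol))
  tab <- table(factor(x$status, levels = c("fixed_ref", "fixed_alt",
                                           "segregating", "missing")))
  cat("  status counts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  markers fixed for the reference allele in every group: %d (%.0f%%)\n",
              x$n_fixed_ref_all_groups,
              100 * x$n_fixed_ref_all_groups / nrow(x$status)))
  invisible(x)
}

#' Per-group mean trait-marker allele frequencies on the 0-1 scale
#'
#' Delegates to [group_mean_af()] on the trait marker subset and rescales
#' percent means to proportions for reporting parity with group-level
#' frequency figures (e.g. AF = 0.43).
#'
#' @inheritParams group_mean_af
#' @param markers Trait marker ids.
#' @return Numeric markers x groups matrix of mean frequencies in [0, 1].
#' @export
trait_af_table <- function(af, sheet, markers, group_by = "subspecies",
                           include_duplicates = TRUE, counts = NULL) {
  means <- group_mean_af(af, sheet, group_by = group_by,
                         include_duplicates = include_duplicates,
                         counts = counts)
  means[markers, , drop = FALSE] / 100
}
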