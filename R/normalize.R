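# Relative quantification by the 2^-ddCt method against one or several
# reference genes. Per biological sample, dCt = Ct_target - Ct_reference;
# ddCt subtracts the mean dCt of the control group's biological replicates.
# With several references the per-reference ddCt values are averaged on the
# Ct scale (for two references this is the familiar
# [(dCt ref1)_exp - (dCt ref1)_ctrl]/2 + [(dCt ref2)_exp - (dCt ref2)_ctrl]/2
# form), which makes the combined fold change the geometric mean of the
# per-reference fold changes. Replicates are averaged before exponentiation,
# on the Ct scale.

#' Relative expression against several reference genes (2^-ddCt)
#'
#' @param ct A replicate-collapsed [ct_matrix()].
#' @param target Target gene id.
#' @param references Character vector of reference gene ids (>= 1; the
#'   duplicated list `c(r, r)` reduces exactly to the single-reference
#'   result).
#' @param control_group Group label of the control (calibrator) samples;
#'   that group's fold change is 1 by construction.
#' @return A data frame of class `relative_expression` with one row per
#'   sample group: `target_gene`, `sample_group`, `delta_delta_ct` (group
#'   mean over biological replicates), `ddct_sd` (SD over replicates),
#'   `fold_change` = `2^(-delta_delta_ct)` and `references_used`.
#' @export
ddct_multi <- function(ct, target, references, control_group) {
  stopifnot(inherits(ct, "ct_matrix"))
  references <- as.character(references)
  if (length(references) < 1L) {
    stop("at least one reference gene is required", call. = FALSE)
  }
  if (target %in% references) {
    stop(sprintf("reference gene must differ from the target ('%s')", target),
         call. = FALSE)
  }
  v <- ct_values(ct)
  missing_genes <- setdiff(c(target, references), rownames(v))
  if (length(missing_genes) > 0L) {
    stop(sprintf("gene(s) not in the Ct matrix: %s",
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  meta <- sample_meta(ct)
  in_control <- meta$group == control_group
  if (!any(in_control)) {
    stop(sprintf("control group '%s' has no samples", control_group),
         call. = FALSE)
  }
  # per-reference ddCt per sample, then average over references
  ddct_per_ref <- vapply(references, function(r) {
    dct <- v[target, ] - v[r, ]
    dct - mean(dct[in_control])
  }, numeric(ncol(v)))
  ddct <- rowMeans(matrix(ddct_per_ref, nrow = ncol(v)))
  groups <- unique(meta$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- ddct[meta$group == g]
    data.frame(target_gene = target, sample_group = g,
               delta_delta_ct = mean(x),
               ddct_sd = if (length(x) > 1L) stats::sd(x) else 0,
               fold_change = 2^(-mean(x)),
               references_used = paste(references, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Relative expression against a single reference gene (2^-ddCt)
#'
#' Convenience wrapper of [ddct_multi()] with one reference.
#'
#' @inheritParams ddct_multi
#' @param reference Reference gene id (must differ from `target`).
#' @return See [ddct_multi()].
#' @examples
#' # experiment: target 24 vs reference 20; control: 26 vs 21
#' # ddCt = 4 - 5 = -1, fold change 2
#' @export
ddct_single <- function(ct, target, reference, control_group) {
  if (length(reference) != 1L) {
    stop("ddct_single takes exactly one reference gene", call. = FALSE)
  }
  ddct_multi(ct, target, references = reference,
             control_group = control_group)
}

#' Compare normalization under stable and unstable references
#'
#' For each target gene and sample group, computes fold changes normalized
#' against each stable reference alone, against their combination, and
#' against the unstable reference — the concordance/discordance contrast used
#' to validate a reference-gene choice: stable references used alone or in
#' combination should agree, while an unstable reference distorts the
#' profile.
#'
#' @param ct A replicate-collapsed [ct_matrix()].
#' @param targets Character vector of target gene ids.
#' @param stable_refs Character vector of validated reference gene ids.
#' @param unstable_ref A deliberately unstable reference gene id.
#' @param control_group Group label of the calibrator samples.
#' @return A data frame with one row per (target, group, normalization
#'   scheme); the `scheme` column is the reference set used.
#' @export
expression_profile <- function(ct, targets, stable_refs, unstable_ref,
                               control_group) {
  schemes <- c(as.list(stable_refs),
               if (length(stable_refs) > 1L) list(stable_refs),
               list(unstable_ref))
  scheme_names <- vapply(schemes, paste, character(1L), collapse = "+")
  out <- do.call(rbind, lapply(targets, function(tg) {
    do.call(rbind, lapply(seq_along(schemes), function(s) {
      res <- ddct_multi(ct, tg, schemes[[s]], control_group)
      res$scheme <- scheme_names[s]
      res
    }))
  }))
  rownames(out) <- NULL
  out
}
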