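# Binarization, spatial extent index, and cross-sectional Braak conformance.

#' Binarize regional SUVR against data-driven cutoffs
#'
#' A region is coded 1 when its SUVR is at or above the regional cutoff
#' (closed lower bound) and 0 below it.
#'
#' @param table A \code{suvr_table}.
#' @param thresholds A \code{threshold_set} covering every region present.
#' @param visit_index Optional single visit to extract (e.g. 0 for
#'   baseline); default all visits.
#' @return A wide data.frame of class \code{binary_pattern}:
#'   \code{subject_id}, \code{visit_index}, \code{years_from_first_scan},
#'   one 0/1 column per region, and \code{spatial_extent} (the row sum).
#' @export
binarize <- function(table, thresholds, visit_index = NULL) {
  if (!is.null(visit_index))
    table <- table[table$visit_index %in% visit_index, ]
  regions <- unique(table$region_id)
  cut <- thresholds$region_cutoffs
  uncovered <- setdiff(regions, names(cut)[is.finite(cut)])
  if (length(uncovered))
    stop("thresholds do not cover region(s): ",
         paste(uncovered, collapse = ", "))
  wide <- stats::reshape(
    table[c("subject_id", "visit_index", "years_from_first_scan",
            "region_id", "suvr")],
    direction = "wide", idvar = c("subject_id", "visit_index",
                                  "years_from_first_scan"),
    timevar = "region_id")
  names(wide) <- sub("^suvr\\.", "", names(wide))
  region_cols <- setdiff(names(wide), c("subject_id", "visit_index",
                                        "years_from_first_scan"))
  for (r in region_cols) wide[[r]] <- as.integer(wide[[r]] >= cut[r])
  wide$spatial_extent <- as.integer(rowSums(wide[region_cols]))
  rownames(wide) <- NULL
  attr(wide, "region_cols") <- region_cols
  class(wide) <- c("binary_pattern", "data.frame")
  wide
}

#' Spatial extent index
#'
#' Number of regions whose SUVR meets or exceeds the regional cutoff —
#' the row sum of the binary pattern matrix.
#'
#' @param pattern A \code{binary_pattern}.
#' @return Named integer vector (names \code{subject_id.visit_index} when
#'   several visits are present, else \code{subject_id}).
#' @export
spatial_extent <- function(pattern) {
  region_cols <- attr(pattern, "region_cols")
  ext <- as.integer(rowSums(pattern[region_cols]))
  nm <- if (length(unique(pattern$visit_index)) > 1L)
    paste(pattern$subject_id, pattern$visit_index, sep = ".")
  else pattern$subject_id
  stats::setNames(ext, nm)
}

#' Binarize Braak-stage composite SUVR
#'
#' @param composites Output of \code{\link{stage_composite_suvr}}.
#' @param thresholds A \code{threshold_set} with stage cutoffs, or a named
#'   numeric vector of stage cutoffs (names \code{stage_I}..\code{stage_VI}).
#' @param visit_index Optional single visit to extract.
#' @return data.frame of class \code{stage_positivity}: \code{subject_id},
#'   \code{visit_index}, 0/1 columns \code{stage_I}, \code{stage_III},
#'   \code{stage_IV}, \code{stage_V}, \code{stage_VI}.
#' @export
stage_positivity <- function(composites, thresholds, visit_index = NULL) {
  cut <- if (inherits(thresholds, "threshold_set"))
    thresholds$stage_cutoffs else thresholds
  if (!is.null(visit_index))
    composites <- composites[composites$visit_index %in% visit_index, ]
  cols <- paste0("stage_", braak_stage_order())
  miss <- cols[!cols %in% names(cut) | !is.finite(cut[cols])]
  if (length(miss))
    stop("missing stage cutoff(s): ", paste(miss, collapse = ", "))
  out <- composites[c("subject_id", "visit_index")]
  for (sc in cols) out[[sc]] <- as.integer(composites[[sc]] >= cut[sc])
  rownames(out) <- NULL
  class(out) <- c("stage_positivity", "data.frame")
  out
}

#' Cross-sectional Braak-staging conformance
#'
#' A subject conforms when positivity at their most advanced (highest)
#' positive Braak stage implies positivity at every earlier stage in the
#' precedence chain I < III < IV < V < VI (stage II is excluded from the
#' chain). Subjects with no positive stage are excluded from all
#' denominators.
#'
#' @param stage_pos A \code{stage_positivity} at a single visit.
#' @param condition How the per-stage percentage conditions subjects:
#'   \code{"highest"} (default) computes, among subjects whose highest
#'   positive stage is s, the share that conform; \code{"positive"}
#'   computes, among subjects positive at stage s, the share positive at
#'   all earlier stages.
#' @return List with \code{per_subject} (subject_id, highest_stage,
#'   conforms), \code{per_stage} (stage, n, pct_conforming),
#'   \code{overall_pct} (share of any-positive subjects conforming), and
#'   \code{n_positive}.
#' @export
braak_conformance_cross <- function(stage_pos,
                                    condition = c("highest", "positive")) {
  condition <- match.arg(condition)
  stages <- braak_stage_order()
  cols <- paste0("stage_", stages)
  m <- as.matrix(stage_pos[cols])
  any_pos <- rowSums(m) > 0
  highest <- apply(m, 1L, function(v) {
    p <- which(v == 1L)
    if (length(p)) max(p) else NA_integer_
  })
  conforms <- vapply(seq_len(nrow(m)), function(i) {
    if (!any_pos[i]) return(NA)
    all(m[i, seq_len(highest[i])] == 1L)
  }, logical(1))

  per_subject <- data.frame(
    subject_id = stage_pos$subject_id,
    highest_stage = ifelse(is.na(highest), NA_character_, stages[highest]),
    conforms = conforms, stringsAsFactors = FALSE)

  per_stage <- do.call(rbind, lapply(seq_along(stages), function(s) {
    if (condition == "highest") {
      idx <- which(!is.na(highest) & highest == s)
      ok <- conforms[idx]
    } else {
      idx <- which(m[, s] == 1L)
      ok <- vapply(idx, function(i) all(m[i, seq_len(s)] == 1L), logical(1))
    }
    data.frame(stage = stages[s], n = length(idx),
               pct_conforming = if (length(idx)) 100 * mean(ok) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  list(per_subject = per_subject,
       per_stage = per_stage,
       overall_pct = if (any(any_pos)) 100 * mean(conforms[any_pos]) else
         NA_real_,
       n_positive = sum(any_pos))
}

#' Export the Fig-3-style heatmap ordering of the binary matrix
#'
#' Rows ordered by diagnostic group then ascending spatial extent; columns
#' (regions) ordered by Braak stage.
#'
#' @param pattern A \code{binary_pattern} at a single visit.
#' @param metadata Subject metadata with \code{diagnosis}.
#' @param registry A \code{region_registry}.
#' @return data.frame ready to write as the heatmap table.
#' @export
heatmap_table <- function(pattern, metadata, registry = region_registry()) {
  region_cols <- attr(pattern, "region_cols")
  stage_rank <- match(registry$braak_stage, c(braak_stage_order(), "none"))
  ord_regions <- registry$region_id[order(stage_rank, registry$region_id)]
  ord_regions <- intersect(ord_regions, region_cols)
  df <- merge(pattern, metadata[c("subject_id", "diagnosis")],
              by = "subject_id")
  df <- df[order(match(df$diagnosis, c("CU", "MCI", "AD")),
                 df$spatial_extent), ]
  out <- df[c("subject_id", "diagnosis", "spatial_extent", ord_regions)]
  rownames(out) <- NULL
  out
}
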