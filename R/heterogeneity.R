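# Between-subject overlap of tau positivity / progression patterns.

#' Jaccard similarity of two positive-region sets
#'
#' |intersection| / |union|. Both sets empty is undefined (callers enforce
#' the at-least-one-positive-region filter upstream).
#'
#' @param a,b Character vectors of positive region ids (or any set
#'   elements).
#' @return Similarity in [0, 1].
#' @export
jaccard_binary <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L)
    stop("Jaccard undefined for two empty sets ",
         "(at-least-one-positive-region filter violated)")
  length(intersect(a, b)) / u
}

#' Jaccard similarity of two progression-state rows
#'
#' Each subject's row is converted to a set of (region, status) pairs with
#' status in {progressor, regressor, stable_positive}; stable_negative
#' agreements are excluded from the set construction by default (including
#' them saturates overlap toward 1 in low-burden groups), switchable via
#' \code{include_stable_negative}.
#'
#' @param a,b Named character vectors of progression states (names =
#'   region ids), e.g. rows of a \code{progression_matrix}.
#' @param include_stable_negative Count stable_negative pairs as set
#'   elements (default FALSE).
#' @return Similarity in [0, 1].
#' @export
jaccard_progression <- function(a, b, include_stable_negative = FALSE) {
  pair_set <- function(v) {
    keep <- if (include_stable_negative) rep(TRUE, length(v))
    else v != "stable_negative"
    paste(names(v)[keep], v[keep], sep = ":")
  }
  jaccard_binary(pair_set(a), pair_set(b))
}

#' Mean within-group pattern overlap
#'
#' For each eligible subject, the mean pairwise Jaccard similarity against
#' every other eligible subject of the same diagnostic group; the group
#' summary is the mean and sd (denominator n-1) of those per-subject means.
#' Eligibility: at least one positive region (binary mode) or at least one
#' region that is not stable_negative (progression mode); ineligible
#' subjects are excluded, never imputed. Groups with fewer than two
#' eligible subjects are skipped with a message.
#'
#' @param patterns \code{binary_pattern} (mode "binary") or
#'   \code{progression_matrix} (mode "progression").
#' @param group_labels Named character vector (names = subject ids) of
#'   group labels, or a data.frame with \code{subject_id} and
#'   \code{diagnosis}.
#' @param mode \code{"binary"} or \code{"progression"}.
#' @param include_stable_negative Passed to
#'   \code{\link{jaccard_progression}}.
#' @return List with \code{per_subject} (subject_id, group, mean_jaccard)
#'   and \code{per_group} (group, n, mean, sd).
#' @export
mean_group_overlap <- function(patterns, group_labels,
                               mode = c("binary", "progression"),
                               include_stable_negative = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(group_labels))
    group_labels <- stats::setNames(group_labels$diagnosis,
                                    group_labels$subject_id)

  if (mode == "binary") {
    region_cols <- attr(patterns, "region_cols")
    sets <- lapply(seq_len(nrow(patterns)), function(i)
      region_cols[patterns[i, region_cols] == 1L])
    names(sets) <- patterns$subject_id
    eligible <- vapply(sets, length, integer(1)) > 0L
  } else {
    sets <- lapply(seq_len(nrow(patterns)), function(i) {
      v <- patterns[i, ]
      keep <- if (include_stable_negative) rep(TRUE, length(v))
      else v != "stable_negative"
      paste(colnames(patterns)[keep], v[keep], sep = ":")
    })
    names(sets) <- rownames(patterns)
    eligible <- vapply(sets, length, integer(1)) > 0L
  }

  subj <- names(sets)[eligible]
  grp <- group_labels[subj]
  if (anyNA(grp)) stop("group label missing for subject(s): ",
                       paste(subj[is.na(grp)], collapse = ", "))

  per_subject <- NULL
  for (g in unique(grp)) {
    ids <- subj[grp == g]
    if (length(ids) < 2L) {
      message("group ", g, " has fewer than 2 eligible subjects; skipped")
      next
    }
    s <- sets[ids]
    nset <- length(ids)
    jm <- matrix(NA_real_, nset, nset)
    for (i in seq_len(nset - 1L)) for (j in seq.int(i + 1L, nset)) {
      jm[i, j] <- jm[j, i] <- jaccard_binary(s[[i]], s[[j]])
    }
    means <- rowMeans(jm, na.rm = TRUE)
    per_subject <- rbind(per_subject, data.frame(
      subject_id = ids, group = g, mean_jaccard = means,
      stringsAsFactors = FALSE))
  }
  if (is.null(per_subject)) stop("no group with >=2 eligible subjects")
  per_group <- do.call(rbind, lapply(split(per_subject, per_subject$group),
    function(d) data.frame(group = d$group[1L], n = nrow(d),
                           mean = mean(d$mean_jaccard),
                           sd = stats::sd(d$mean_jaccard),
                           stringsAsFactors = FALSE)))
  rownames(per_group) <- rownames(per_subject) <- NULL
  list(per_subject = per_subject, per_group = per_group, mode = mode)
}
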