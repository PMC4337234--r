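#' Node scores for one valence
#'
#' Reduces the six averaged CHANGE variables of one valence to the four
#' pattern nodes. The cognitive node is the arithmetic mean of View of Self,
#' Hope, and Relationships (the cognitive triad: self, future, others); the
#' emotion, behavior, and somatic nodes are the corresponding single
#' variables. All node values lie in [0, 3].
#'
#' If some but not all cognitive source variables are missing the mean is
#' taken over the available ones; a node with no available source stays `NA`
#' and marks downstream profiles incomputable.
#'
#' @param averaged Averaged coding `data.frame` from [average_coders()] (any
#'   number of rows).
#' @param valence `"negative"` or `"positive"`.
#' @return `data.frame` with columns `patient_id`, `session_number`,
#'   `valence`, `cognitive`, `emotion`, `behavior`, `somatic`.
#' @export
#' @examples
#' a <- data.frame(patient_id = "p1", session_number = 1,
#'   neg_view_self = 3, neg_hope = 2, neg_relationships = 1,
#'   neg_emotion = 2, neg_behavior = 1, neg_somatic = 0)
#' node_scores(a, "negative")$cognitive  # 2
node_scores <- function(averaged, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  pre <- if (valence == "negative") "neg_" else "pos_"
  col <- function(v) {
    nm <- paste0(pre, v)
    if (nm %in% names(averaged)) averaged[[nm]] else rep(NA_real_, nrow(averaged))
  }
  cog <- cbind(col("view_self"), col("hope"), col("relationships"))
  cognitive <- rowMeans(cog, na.rm = TRUE)
  cognitive[!is.finite(cognitive)] <- NA_real_
  data.frame(
    patient_id = averaged$patient_id,
    session_number = averaged$session_number,
    valence = valence,
    cognitive = cognitive,
    emotion = as.numeric(col("emotion")),
    behavior = as.numeric(col("behavior")),
    somatic = as.numeric(col("somatic")),
    stringsAsFactors = FALSE
  )
}

.node_matrix <- function(nodes) {
  if (is.data.frame(nodes)) {
    as.matrix(nodes[c("cognitive", "emotion", "behavior", "somatic")])
  } else if (is.numeric(nodes) && length(nodes) == 4L) {
    matrix(nodes, nrow = 1L,
      dimnames = list(NULL, c("cognitive", "emotion", "behavior", "somatic")))
  } else {
    stop("nodes must be a node-score data.frame or a numeric vector of 4",
      call. = FALSE)
  }
}

#' Pattern strength
#'
#' The strength of one valence's pattern in a session: the sum of the four
#' node values (cognitive, emotion, behavior, somatic), range 0-12. A missing
#' node makes the strength `NA` (incomputable), never a rescaled partial sum.
#'
#' @param nodes Output of [node_scores()] (row-wise), or a numeric vector of
#'   the four node values.
#' @return Numeric vector of strengths in [0, 12].
#' @export
#' @examples
#' pattern_strength(c(3, 3, 3, 1)) # 10
pattern_strength <- function(nodes) {
  m <- .node_matrix(nodes)
  unname(rowSums(m))
}

#' Pattern activation score
#'
#' The breadth of one valence's pattern in a session: how many of the four
#' nodes are engaged at a moderate-to-high level (CHANGE rating 2 or 3).
#' Activation ranges 0 (no node at threshold) to 4 (all nodes above
#' threshold) and is the grid coordinate of a session on the state-space
#' grid. The comparison is a strict `>= threshold`, so an averaged half-point
#' of 1.5 does not activate while 2.0 does.
#'
#' @inheritParams pattern_strength
#' @param threshold Activation floor on the node score, default 2.
#' @return Integer vector of activation counts in 0..4 (`NA` if any node is
#'   missing).
#' @export
#' @examples
#' activation_score(c(3, 3, 3, 1)) # 3
activation_score <- function(nodes, threshold = 2) {
  m <- .node_matrix(nodes)
  out <- rowSums(m >= threshold)
  out[apply(m, 1L, anyNA)] <- NA
  as.integer(unname(out))
}

#' Per-session pattern profiles for both valences
#'
#' Applies the node reduction, strength, and activation scoring to every
#' averaged session for both the negative and the positive pattern. The
#' resulting (positive activation, negative activation) pair is the session's
#' point on the 5x5 state-space grid.
#'
#' `cognitive_activation` selects how the cognitive node meets the
#' activation threshold: `"node-mean"` (default) thresholds the averaged
#' cognitive node score; `"per-variable"` thresholds the three cognitive
#' variables individually and counts the node as activated when a majority
#' (at least two of three available) reach it.
#'
#' @param averaged Averaged coding `data.frame` from [average_coders()].
#' @param threshold Activation floor, default 2.
#' @param cognitive_activation `"node-mean"` or `"per-variable"`.
#' @return Long `data.frame`: `patient_id`, `session_number`, `valence`,
#'   `cognitive`, `emotion`, `behavior`, `somatic`, `strength`, `activation`,
#'   `processing` (the averaged processing rating, repeated per valence).
#' @export
session_profiles <- function(averaged, threshold = 2,
                             cognitive_activation = c("node-mean", "per-variable")) {
  cognitive_activation <- match.arg(cognitive_activation)
  one <- function(valence) {
    nd <- node_scores(averaged, valence)
    nd$strength <- pattern_strength(nd)
    nd$activation <- activation_score(nd, threshold)
    if (cognitive_activation == "per-variable") {
      pre <- if (valence == "negative") "neg_" else "pos_"
      cogv <- as.matrix(averaged[paste0(pre,
        c("view_self", "hope", "relationships"))])
      n_at <- rowSums(cogv >= threshold, na.rm = TRUE)
      n_ok <- rowSums(!is.na(cogv))
      cog_active <- !is.na(nd$cognitive) & n_at >= pmax(2L, ceiling(n_ok / 2))
      others <- as.matrix(nd[c("emotion", "behavior", "somatic")])
      act <- rowSums(others >= threshold) + cog_active
      act[apply(others, 1L, anyNA) | is.na(nd$cognitive)] <- NA
      nd$activation <- as.integer(act)
    }
    nd$processing <- if ("processing" %in% names(averaged)) {
      as.numeric(averaged$processing)
    } else {
      NA_real_
    }
    nd
  }
  out <- rbind(one("positive"), one("negative"))
  out <- out[order(out$patient_id, out$session_number,
    match(out$valence, c("positive", "negative"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-patient activation points for one phase
#'
#' Convenience pivot of [session_profiles()] output to one row per session
#' with the grid coordinates: `x` = positive activation, `y` = negative
#' activation.
#'
#' @param profiles Output of [session_profiles()].
#' @return `data.frame` with `patient_id`, `session_number`, `x`, `y`,
#'   `processing`.
#' @export
activation_points <- function(profiles) {
  pos <- profiles[profiles$valence == "positive", ]
  neg <- profiles[profiles$valence == "negative", ]
  key <- paste(pos$patient_id, pos$session_number, sep = "\r")
  nkey <- paste(neg$patient_id, neg$session_number, sep = "\r")
  neg <- neg[match(key, nkey), ]
  data.frame(
    patient_id = pos$patient_id,
    session_number = pos$session_number,
    x = pos$activation,
    y = neg$activation,
    processing = pos$processing,
    stringsAsFactors = FALSE
  )
}
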