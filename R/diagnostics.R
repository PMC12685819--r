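# Post-hoc interpretation of predicted VAD triples: rule-based six-state
# labeling, Fatigue Index, Motion Quality, and k-means profiling of the
# normalized VAD space. All inputs are on the normalized [0,1] scale.

#' Default rule thresholds for the six emotional states
#'
#' The rule structure (arousal/valence thresholds, dominance consulted for
#' passivity) is fixed; these numeric defaults are a reconstruction fitted to
#' reproduce the published worked examples, not authorial values, and any
#' consistent alternative can be supplied instead.
#'
#' @return named list of thresholds, all in `[0, 1]`.
#' @export
rule_thresholds <- function() {
  list(happy_arousal_min = 0.6, happy_valence_min = 0.7,
       stressed_arousal_min = 0.6, stressed_valence_max = 0.4,
       relaxed_arousal_max = 0.3, relaxed_valence_min = 0.7,
       fatigued_arousal_max = 0.3, fatigued_valence_max = 0.3,
       passive_arousal_below = 0.4, passive_dominance_below = 0.5)
}

#' States assignable by the rule engine
#' @return character vector in precedence order.
#' @export
vad_states <- function() {
  c("Happy/Excited", "Stressed", "Relaxed", "Fatigued", "Passive", "Neutral")
}

#' Map a normalized VAD triple to an emotional state
#'
#' Rules are evaluated in fixed precedence order -- Happy/Excited, Stressed,
#' Relaxed, Fatigued, Passive, Neutral -- and the first match wins (so a
#' point satisfying both Relaxed and Passive is Relaxed). Min/max thresholds
#' are inclusive; the "below" thresholds of the Passive rule are strict.
#' Dominance is consulted only by the Passive rule.
#'
#' @param arousal,valence,dominance components in `[0, 1]`.
#' @param thresholds a threshold list as from [rule_thresholds()].
#' @return one of [vad_states()].
#' @export
rule_based_state <- function(arousal, valence, dominance,
                             thresholds = rule_thresholds()) {
  v <- c(arousal, valence, dominance)
  if (any(v < 0) || any(v > 1)) stopf("VAD components must lie in [0, 1]")
  th <- thresholds
  if (arousal >= th$happy_arousal_min && valence >= th$happy_valence_min)
    return("Happy/Excited")
  if (arousal >= th$stressed_arousal_min && valence <= th$stressed_valence_max)
    return("Stressed")
  if (arousal <= th$relaxed_arousal_max && valence >= th$relaxed_valence_min)
    return("Relaxed")
  if (arousal <= th$fatigued_arousal_max && valence <= th$fatigued_valence_max)
    return("Fatigued")
  if (arousal < th$passive_arousal_below && dominance < th$passive_dominance_below)
    return("Passive")
  "Neutral"
}

#' Fatigue Index
#'
#' The inverse of the normalized arousal score: `1 - arousal`. Higher values
#' indicate greater estimated fatigue.
#'
#' @param arousal normalized arousal in `[0, 1]` (vectorized).
#' @return `1 - arousal`.
#' @export
fatigue_index <- function(arousal) {
  if (any(arousal < 0) || any(arousal > 1)) stopf("arousal must lie in [0, 1]")
  1 - arousal
}

#' Motion Quality score
#'
#' The product of valence and dominance: a scalar measure of how positively
#' and assertively a user engages, bounded in `[0, 1]` and monotone in each
#' argument.
#'
#' @param valence,dominance components in `[0, 1]` (vectorized).
#' @return `valence * dominance`.
#' @export
motion_quality <- function(valence, dominance) {
  if (any(c(valence, dominance) < 0) || any(c(valence, dominance) > 1))
    stopf("valence and dominance must lie in [0, 1]")
  valence * dominance
}

# k-means++ initial centers (seeded by the caller)
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(x, 1, function(r) min(colSums((t(centers) - r)^2)))
    centers <- rbind(centers, x[sample.int(n, 1, prob = d2 / sum(d2)), ])
  }
  centers
}

#' Cluster normalized VAD triples with k-means
#'
#' k-means (Lloyd iterations via [stats::kmeans()]) with k-means++ seeding,
#' 10 restarts and a fixed seed; the best restart by total within-cluster
#' sum of squares wins. Four clusters by default.
#'
#' @param vad_matrix numeric matrix (n x 3) of normalized VAD rows.
#' @param k number of clusters (default 4; requires `n >= k`).
#' @param seed integer seed.
#' @param restarts k-means++ restarts (default 10).
#' @return integer cluster labels in `{0, ..., k-1}`.
#' @export
cluster_states <- function(vad_matrix, k = 4, seed = 1, restarts = 10) {
  x <- as.matrix(vad_matrix)
  if (nrow(x) < k) stopf("need at least k = %d rows, got %d", k, nrow(x))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    cs <- .kmeanspp_centers(x, k)
    km <- suppressWarnings(stats::kmeans(x, centers = cs, iter.max = 100,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  as.integer(best$cluster) - 1L
}

#' Full diagnostic table for predicted VAD triples
#'
#' Per row: the rule-based state, k-means cluster, Fatigue Index
#' (`1 - arousal`) and Motion Quality (`valence * dominance`). Values are
#' kept at full precision; use `display = TRUE` for the 2-decimal
#' half-away-from-zero rounding of the printed table format.
#'
#' @param vad_matrix n x 3 matrix, columns valence, arousal, dominance, in
#'   `[0, 1]` (column names, if present, may be in any order).
#' @param thresholds rule thresholds (default [rule_thresholds()]).
#' @param k clusters (default 4).
#' @param seed clustering seed.
#' @param display round numeric columns to 2 decimals for display.
#' @return data.frame with columns sample, arousal, valence, dominance,
#'   state, cluster, fatigue_index, motion_quality.
#' @export
diagnose <- function(vad_matrix, thresholds = rule_thresholds(), k = 4,
                     seed = 1, display = FALSE) {
  x <- as.matrix(vad_matrix)
  if (ncol(x) != 3) stopf("vad_matrix must have 3 columns")
  if (nrow(x) == 0)
    return(data.frame(sample = integer(0), arousal = numeric(0),
                      valence = numeric(0), dominance = numeric(0),
                      state = character(0), cluster = integer(0),
                      fatigue_index = numeric(0), motion_quality = numeric(0)))
  cn <- colnames(x)
  if (!is.null(cn) && all(c("valence", "arousal", "dominance") %in% cn))
    x <- x[, c("valence", "arousal", "dominance"), drop = FALSE]
  if (any(x < 0) || any(x > 1)) stopf("VAD rows must lie in [0, 1]^3")
  states <- vapply(seq_len(nrow(x)), function(i)
    rule_based_state(x[i, 2], x[i, 1], x[i, 3], thresholds), "")
  clusters <- if (nrow(x) >= k) cluster_states(x, k, seed) else rep(NA_integer_, nrow(x))
  out <- data.frame(sample = seq_len(nrow(x)) - 1L,
                    arousal = x[, 2], valence = x[, 1], dominance = x[, 3],
                    state = states, cluster = clusters,
                    fatigue_index = fatigue_index(x[, 2]),
                    motion_quality = motion_quality(x[, 1], x[, 3]))
  if (display) {
    num <- c("arousal", "valence", "dominance", "fatigue_index", "motion_quality")
    out[num] <- lapply(out[num], round_half_away, digits = 2)
  }
  out
}
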