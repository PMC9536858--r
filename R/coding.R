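# Breadth of tuning, chemosensitive clustering, profile stability across
# light conditions, and across-neuron ensemble analysis with
# multidimensional scaling.

#' Net-response matrix across units
#'
#' Assembles a units x stimuli matrix of net responses for one light
#' condition from a list of response profiles — the common input to the
#' clustering and ensemble operations.
#'
#' @param profiles List of [response_profile] objects.
#' @param condition Light condition to extract (default `"control"`).
#' @param stimuli Stimulus order; default the order of the first profile.
#' @return Numeric matrix, rownames = unit ids, colnames = stimuli.
#' @export
profile_matrix <- function(profiles, condition = "control", stimuli = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(stimuli)) {
    p1 <- profiles[[1]]
    stimuli <- unique(p1$stimulus[p1$light_condition == condition])
  }
  rows <- lapply(profiles, function(p) {
    sub <- p[p$light_condition == condition, , drop = FALSE]
    v <- sub$net_spikes_per_window[match(stimuli, sub$stimulus)]
    names(v) <- stimuli
    v
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(profiles, function(p) attr(p, "unit_id"), character(1))
  mat
}

#' Response entropy (breadth of tuning)
#'
#' `H = -K * sum(P_i * log10(P_i))` over a profile's net responses, where
#' `P_i` is the proportion of the summed responses arising from stimulus i
#' and `K = 1.43 ~ 1/log10(5)`, so a uniform five-stimulus profile scores
#' ~1 and a single-stimulus profile ~0. The entropy cannot accommodate
#' zeros or negative numbers, so responses <= 0 are replaced by a very
#' small value — `epsilon_frac` times the sum of the positive responses —
#' before forming the proportions.
#'
#' @param responses Numeric net responses, one per stimulus.
#' @param epsilon_frac Zero/negative substitution fraction (default 1e-6).
#' @param K Scale constant (default 1.43).
#' @return H, with attribute `P` (the proportions used). `NA` (with
#'   attribute `defined = FALSE`) when no response is positive.
#' @export
response_entropy <- function(responses, epsilon_frac = 1e-6, K = 1.43) {
  if (!any(responses > 0)) {
    return(structure(NA_real_, defined = FALSE))
  }
  eps <- epsilon_frac * sum(responses[responses > 0])
  r <- ifelse(responses <= 0, eps, responses)
  P <- r / sum(r)
  structure(-K * sum(P * log10(P)), P = P, defined = TRUE)
}

#' Breadth-of-tuning metrics for one unit
#'
#' Three measures of how broadly a cell is tuned across the stimulus panel:
#' (1) the number of stimuli whose response passed the response criterion;
#' (2) the noise:signal ratio, second-best response / best response over
#' the panel's included stimuli (negative responses floored at zero; the
#' panel's excluded stimuli — MSGai on the standard panels — are omitted);
#' (3) the response entropy `H = -K * sum(P_i * log10(P_i))` with `K =
#' 1.43`, where `P_i` is the proportion of the summed responses arising
#' from stimulus i. K = 1.43 ~ 1/log10(5) scales H to ~1 for a uniform
#' five-stimulus profile. Because the entropy cannot accommodate zeros or
#' negative numbers, responses <= 0 are replaced by a very small value
#' (`epsilon_frac` times the sum of the positive responses) before forming
#' the proportions. A cell with no positive response is entirely
#' unresponsive: its H and N:S are undefined and flagged.
#'
#' @param profile A flagged [response_profile] (see [flag_responses()]); the
#'   `significant` column feeds the response count.
#' @param condition Light condition to evaluate.
#' @param panel A [stimulus_panel] (supplies the N:S exclusion list).
#' @param epsilon_frac Zero/negative substitution, as a fraction of the
#'   summed positive responses (default 1e-6).
#' @param entropy_K Entropy scale constant (default 1.43).
#' @return One-row data frame of class `tuning_metrics`: `unit_id`,
#'   `light_condition`, `n_significant`, `ns_ratio`, `entropy_H`,
#'   `defined` (FALSE for an entirely unresponsive cell); attribute `P`
#'   holds the proportions used for H.
#' @examples
#' # a profile responding equally to all 5 stimuli has H ~ 1
#' @export
tuning_metrics <- function(profile, condition = "control", panel,
                           epsilon_frac = 1e-6, entropy_K = 1.43) {
  stopifnot(inherits(panel, "stimulus_panel"))
  sub <- profile[profile$light_condition == condition, , drop = FALSE]
  if (nrow(sub) < 2) stop("need >= 2 stimuli for tuning metrics", call. = FALSE)
  r <- sub$net_spikes_per_window[match(panel$stimuli, sub$stimulus)]
  names(r) <- panel$stimuli
  r <- r[!is.na(r)]

  n_sig <- if ("significant" %in% names(sub)) {
    sum(sub$significant)
  } else NA_integer_

  H <- response_entropy(r, epsilon_frac, entropy_K)
  defined <- isTRUE(attr(H, "defined"))
  P <- if (defined) attr(H, "P") else rep(NA_real_, length(r))
  H <- as.numeric(H)

  incl <- setdiff(names(r), panel$exclude_from_ns)
  ri <- pmax(r[incl], 0)
  ns <- if (length(ri) >= 2 && max(ri) > 0) {
    srt <- sort(ri, decreasing = TRUE)
    srt[2] / srt[1]
  } else NA_real_

  out <- data.frame(
    unit_id = attr(profile, "unit_id") %||% NA_character_,
    light_condition = condition,
    n_significant = n_sig,
    ns_ratio = ns,
    entropy_H = H,
    defined = defined
  )
  class(out) <- c("tuning_metrics", class(out))
  attr(out, "P") <- P
  out
}

#' Hierarchical clustering of chemosensitive profiles
#'
#' Clusters units by the shape of their response profiles: pairwise
#' distance `1 - Pearson r` between net-response vectors (so the clustering
#' is invariant to overall response magnitude) and average-linkage
#' agglomeration. Constant (zero-variance) profiles have no defined
#' correlation and are excluded with a warning. The amalgamation schedule
#' (scree) is returned for choosing the number of groups; no automatic cut
#' is applied by default, but [cluster_cut()] offers a chosen `k` and a
#' largest-gap heuristic.
#'
#' @param profiles List of [response_profile] objects, or a units x stimuli
#'   numeric matrix of net responses.
#' @param condition Light condition (used when `profiles` is a list).
#' @return List of class `cluster_result`: `hclust` (the tree, heights in
#'   `1 - r` units), `scree` (amalgamation distances in merge order),
#'   `excluded` (ids of constant profiles), `matrix` (the profiles used).
#' @export
cluster_profiles <- function(profiles, condition = "control") {
  mat <- if (is.matrix(profiles)) profiles else profile_matrix(profiles, condition)
  if (ncol(mat) < 3) stop("need >= 3 stimuli for profile correlation", call. = FALSE)
  vr <- apply(mat, 1, stats::var)
  excluded <- rownames(mat)[vr == 0 | is.na(vr)]
  if (length(excluded)) {
    warning("excluding constant profile(s): ",
            paste(excluded, collapse = ", "), call. = FALSE)
    mat <- mat[!(rownames(mat) %in% excluded), , drop = FALSE]
  }
  if (nrow(mat) < 3) stop("need >= 3 usable profiles", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "average")
  structure(
    list(hclust = hc, scree = hc$height, excluded = excluded, matrix = mat),
    class = "cluster_result"
  )
}

#' @rdname cluster_profiles
#' @param result A `cluster_result`.
#' @param k Number of flat clusters; `NULL` selects k at the largest gap in
#'   the amalgamation schedule (a heuristic stand-in for consulting the
#'   scree plot).
#' @return `cluster_cut()`: named integer vector of cluster labels, with a
#'   `means` attribute holding each cluster's mean profile.
#' @export
cluster_cut <- function(result, k = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  h <- result$hclust
  if (is.null(k)) {
    gaps <- diff(h$height)
    k <- length(h$height) + 1L - which.max(gaps)
  }
  labels <- stats::cutree(h, k = k)
  means <- do.call(rbind, lapply(split(
    as.data.frame(result$matrix), labels), colMeans))
  attr(labels, "means") <- as.matrix(means)
  labels
}

#' @rdname cluster_profiles
#' @return `cluster_newick()`: the linkage tree as a newick string (branch
#'   lengths in `1 - r` units).
#' @export
cluster_newick <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  ape::write.tree(ape::as.phylo(result$hclust))
}

#' Per-unit profile stability across light conditions
#'
#' Pearson correlation between a unit's control and brain-light response
#' profiles. Purely divisive suppression leaves the profile shape intact
#' (r = 1); a zero-variance profile in either condition has no defined
#' correlation and is flagged.
#'
#' @param profiles List of [response_profile] objects with both conditions.
#' @return Data frame: `unit_id`, `r`, `defined`.
#' @export
profile_stability <- function(profiles) {
  if (inherits(profiles, "response_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    ctrl <- p[p$light_condition == "control", , drop = FALSE]
    lt <- p[p$light_condition == "light_br", , drop = FALSE]
    if (!nrow(ctrl) || !nrow(lt)) {
      stop("profile lacks one of the two light conditions", call. = FALSE)
    }
    v1 <- ctrl$net_spikes_per_window
    v2 <- lt$net_spikes_per_window[match(ctrl$stimulus, lt$stimulus)]
    ok <- stats::var(v1) > 0 && stats::var(v2, na.rm = TRUE) > 0
    data.frame(unit_id = attr(p, "unit_id") %||% NA_character_,
               r = if (ok) stats::cor(v1, v2) else NA_real_,
               defined = ok)
  })
  do.call(rbind, rows)
}

#' Across-neuron ensemble pattern and multidimensional scaling
#'
#' Treats each stimulus x condition as a point described by its vector of
#' net responses across taste-responsive neurons. Computes the stimulus x
#' stimulus Pearson correlation matrix within each condition, the
#' within-stimulus correlation across conditions (how closely the
#' brain-light representation of a stimulus tracks its control
#' representation), and classical (metric) MDS coordinates on the pooled
#' `1 - r` distances. Coordinates are centered; each axis's sign is fixed
#' so the first stimulus's control point is nonnegative on it. Classical
#' scaling was chosen for determinism; [stats::isoMDS] users can feed the
#' returned distance matrix to a nonmetric variant.
#'
#' @param profiles List of [response_profile] objects (>= 3 units
#'   recommended; fewer than 2 is an error), or a list with elements
#'   `control` and `light_br`, each a stimuli x neurons matrix.
#' @param conditions Conditions to include (default both).
#' @param dims MDS dimensionality (default 2).
#' @return List of class `ensemble_pattern`: `correlations` (per-condition
#'   stimulus x stimulus matrices), `cross_condition` (named per-stimulus
#'   r), `mds` (coordinates, rows named `<stimulus>.<condition>`),
#'   `distances` (the `1 - r` matrix fed to MDS).
#' @export
ensemble_mds <- function(profiles, conditions = c("control", "light_br"),
                         dims = 2) {
  if (is.list(profiles) && !is.null(profiles$control)) {
    mats <- lapply(profiles[conditions], function(m) t(as.matrix(m)))
  } else {
    mats <- lapply(conditions, function(cond) profile_matrix(profiles, cond))
    names(mats) <- conditions
  }
  n_units <- nrow(mats[[1]])
  if (n_units < 2) stop("need >= 2 neurons for across-neuron correlations",
                        call. = FALSE)

  # stimulus x stimulus correlations across neurons, per condition
  correlations <- lapply(mats, function(m) stats::cor(m))

  cross <- NULL
  if (all(c("control", "light_br") %in% names(mats))) {
    stim <- colnames(mats$control)
    cross <- vapply(stim, function(s) {
      stats::cor(mats$control[, s], mats$light_br[, s])
    }, double(1))
  }

  pooled <- do.call(cbind, lapply(names(mats), function(cond) {
    m <- mats[[cond]]
    colnames(m) <- paste(colnames(m), cond, sep = ".")
    m
  }))
  D <- 1 - stats::cor(pooled)
  coords <- stats::cmdscale(stats::as.dist(D), k = dims)
  coords <- scale(coords, center = TRUE, scale = FALSE)
  for (j in seq_len(ncol(coords))) {
    if (coords[1, j] < 0) coords[, j] <- -coords[, j]
  }
  structure(
    list(correlations = correlations, cross_condition = cross,
         mds = coords, distances = D),
    class = "ensemble_pattern"
  )
}
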