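# Position decoding: a radial-basis-function SVM (libsvm via e1071;
# one-vs-one is libsvm's native multiclass scheme) predicts the sequence
# position from phase-of-firing features, with repeated stratified 85/15
# splits and a label-shuffle null. Circular features are embedded as
# (cos theta, sin theta) so wrap-around continuity is preserved.

#' Embed phases on the unit circle
#' @param phases radians; vector or matrix (trials x units).
#' @return matrix with cos/sin column pairs.
#' @export
phase_features <- function(phases) {
  m <- as.matrix(phases)
  out <- matrix(NA_real_, nrow(m), 2L * ncol(m))
  for (j in seq_len(ncol(m))) {
    out[, 2L * j - 1L] <- cos(m[, j])
    out[, 2L * j] <- sin(m[, j])
  }
  colnames(out) <- paste0(rep(c("cos", "sin"), ncol(m)),
                          rep(seq_len(ncol(m)), each = 2L))
  out
}

# RBF scale by the median-pairwise-distance heuristic (fixed, deterministic)
rbf_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200L) seq(1L, n, length.out = 200L) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med <= 0) return(1)
  1 / (2 * med^2)
}

# one stratified split: indices of the training set
stratified_split <- function(labels, train_frac) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    n_tr <- max(1L, floor(length(ix) * train_frac))
    if (n_tr >= length(ix)) n_tr <- length(ix) - 1L
    sample(ix, n_tr)
  }), use.names = FALSE)
}

#' Decode position labels from features
#'
#' Repeated stratified train/test splits (85/15 by default); accuracy is
#' the mean held-out fraction correct across repeats.
#'
#' @param features numeric matrix (trials x features), e.g. from
#'   [phase_features()]; a vector of raw phases is embedded automatically.
#' @param labels class labels (positions 1-4), >= 2 trials per class.
#' @param train_frac training fraction (default 0.85).
#' @param n_repeats split repeats (default 20).
#' @param seed RNG seed.
#' @param cost SVM regularization (default 1).
#' @return list of class `decoding_result` with `accuracy` (mean),
#'   `accuracy_per_repeat`, `n`, `chance`.
#' @export
decode_position <- function(features, labels, train_frac = 0.85,
                            n_repeats = 20L, seed = 1L, cost = 1) {
  if (is.null(dim(features))) features <- phase_features(features)
  labels <- factor(labels)
  if (any(table(labels) < 2L))
    stop_param("decode_position: need >= 2 trials per class")
  if (nrow(features) != length(labels))
    stop_param("decode_position: feature/label length mismatch")
  gam <- rbf_gamma(features)
  acc <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      for (attempt in 1:20) {
        tr <- stratified_split(labels, train_frac)
        if (nlevels(droplevels(labels[tr])) == nlevels(labels) &&
            length(tr) < length(labels)) break
      }
      te <- setdiff(seq_along(labels), tr)
      fit <- e1071::svm(x = features[tr, , drop = FALSE], y = labels[tr],
                        kernel = "radial", gamma = gam, cost = cost,
                        scale = FALSE)
      pred <- stats::predict(fit, features[te, , drop = FALSE])
      mean(pred == labels[te])
    }, numeric(1))
  })
  structure(list(accuracy = mean(acc), accuracy_per_repeat = acc,
                 n = length(labels), chance = 1 / nlevels(labels)),
            class = "decoding_result")
}

#' Label-shuffle null for decoding accuracy
#'
#' Permutes labels across trials `n_shuffles` times, re-running the full
#' decoder each time; p is the add-one rank of the observed accuracy in
#' the null.
#'
#' @param features,labels,train_frac,seed as [decode_position()].
#' @param n_shuffles number of label permutations (default 101; 199 is
#'   used for rate-based decoding).
#' @param n_repeats split repeats per decode (default 5 within the null
#'   for tractability).
#' @param observed optional precomputed `decoding_result` for the true
#'   labels; computed here if missing.
#' @return list with `observed`, `null` (accuracies), `null_mean`, `p`.
#' @export
shuffle_null <- function(features, labels, n_shuffles = 101L, seed = 1L,
                         train_frac = 0.85, n_repeats = 5L,
                         observed = NULL) {
  if (n_shuffles < 20L)
    warning("shuffle_null: fewer than 20 shuffles gives a coarse p-value")
  if (is.null(dim(features))) features <- phase_features(features)
  if (is.null(observed))
    observed <- decode_position(features, labels, train_frac = train_frac,
                                n_repeats = max(n_repeats, 10L), seed = seed)
  shuffles <- with_seed(substream_seed(seed, "label_shuffles"), {
    lapply(seq_len(n_shuffles), function(s) sample(seq_along(labels)))
  })
  null <- vapply(seq_len(n_shuffles), function(s) {
    decode_position(features, labels[shuffles[[s]]],
                    train_frac = train_frac, n_repeats = n_repeats,
                    seed = substream_seed(seed, paste0("shuffle", s)))$accuracy
  }, numeric(1))
  p <- (1 + sum(null >= observed$accuracy)) / (1 + n_shuffles)
  list(observed = observed, null = null, null_mean = mean(null), p = p)
}

#' Assemble a pseudo-population feature matrix
#'
#' Units recorded in different sessions are combined by sampling trials
#' without replacement within each position class (pseudo-trials), then
#' concatenating each unit's cos/sin phase features. Units lacking
#' `trials_per_class` trials in any class are dropped (reported).
#'
#' @param sample_sets list of [phase_sample_set()], one per unit.
#' @param trials_per_class pseudo-trials per class (default: the minimum
#'   class count across retained units).
#' @param seed RNG seed.
#' @return list with `features` (pseudo-trials x 2*n_units), `labels`,
#'   `units_used`, `units_dropped`.
#' @export
pseudo_population <- function(sample_sets, trials_per_class = NULL,
                              seed = 1L) {
  if (length(sample_sets) < 2L)
    stop_param("pseudo_population: need >= 2 units")
  classes <- sort(unique(unlist(lapply(sample_sets,
                                       function(s) s$condition))))
  counts <- sapply(sample_sets, function(s)
    min(sapply(classes, function(k) sum(s$condition == k))))
  if (is.null(trials_per_class)) {
    keep <- counts >= 2L
    trials_per_class <- min(counts[keep])
  } else {
    keep <- counts >= trials_per_class
  }
  if (sum(keep) < 2L)
    stop_param("pseudo_population: fewer than 2 units with enough trials")
  used <- which(keep)
  with_seed(substream_seed(seed, "pseudo_population"), {
    labels <- rep(classes, each = trials_per_class)
    feats <- lapply(used, function(u) {
      s <- sample_sets[[u]]
      ph <- unlist(lapply(classes, function(k) {
        cand <- s$phase[s$condition == k]
        cand[sample.int(length(cand), trials_per_class)]
      }))
      phase_features(ph)
    })
    list(features = do.call(cbind, feats), labels = labels,
         units_used = used, units_dropped = which(!keep))
  })
}
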