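# Class-balanced random forest beat classifier (ranger backend) and
# the AAMI five-class grouping of MIT-BIH beat symbols.

#' Gini impurity of a class-probability vector
#'
#' `1 - sum(p_i^2)`; the split-quality criterion used by the forest.
#'
#' @param p Probability vector (sums to 1).
#' @return Scalar impurity in `[0, 1 - 1/length(p)]`.
#' @export
gini_impurity <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  1 - sum(p^2)
}

#' Balanced per-sample weights
#'
#' The weight of class c is `N_total / (C * N_c)` (inversely
#' proportional to class frequency); each sample gets its class
#' weight, so every class carries equal total weight and the weights
#' sum to `N_total`.
#'
#' @param labels Class labels.
#' @return Numeric weight per sample.
#' @export
balanced_weights <- function(labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) >= 1)
  tab <- table(labels)
  w <- length(labels) / (length(tab) * tab)
  as.numeric(w[labels])
}

#' AAMI symbol-to-class map
#'
#' The ANSI/AAMI EC57 grouping of the 15 MIT-BIH beat symbols into 5
#' classes: `{N,L,R,e,j} -> N`, `{A,a,J,S} -> SVEB`, `{V,E} -> VEB`,
#' `{F} -> F`, `{/,f,Q} -> Q`.
#'
#' @return Named character vector (symbol -> class).
#' @export
aami_map <- function() {
  c("N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
    "A" = "SVEB", "a" = "SVEB", "J" = "SVEB", "S" = "SVEB",
    "V" = "VEB", "E" = "VEB",
    "F" = "F",
    "/" = "Q", "f" = "Q", "Q" = "Q")
}

#' Group beat symbols into AAMI classes
#'
#' @param symbols Character vector of MIT-BIH beat symbols.
#' @return Character vector of AAMI classes (`N`, `SVEB`, `VEB`, `F`,
#'   `Q`); unknown symbols are an error.
#' @export
aami_group <- function(symbols) {
  m <- aami_map()
  out <- m[as.character(symbols)]
  if (anyNA(out)) {
    stop("symbols outside the AAMI 15-symbol alphabet: ",
         paste(unique(symbols[is.na(out)]), collapse = " "))
  }
  unname(out)
}

#' The standard DS1/DS2 inter-patient division of MIT-BIH
#'
#' The customary train/test split of the 44 non-paced MIT-BIH
#' Arrhythmia records: no patient contributes beats to both sides.
#'
#' @return List with character vectors `train` (DS1) and `test` (DS2).
#' @export
mitbih_split <- function() {
  list(
    train = c("101", "106", "108", "109", "112", "114", "115", "116",
              "118", "119", "122", "124", "201", "203", "205", "207",
              "208", "209", "215", "220", "223", "230"),
    test = c("100", "103", "105", "111", "113", "117", "121", "123",
             "200", "202", "210", "212", "213", "214", "219", "221",
             "222", "228", "231", "232", "233", "234"))
}

#' Train the class-balanced random forest
#'
#' A bagged forest of `n_trees` Gini-split trees with
#' `mtry = floor(sqrt(m))` candidate features per split and balanced
#' per-sample weights. Factor columns (the categorical segment-label
#' ID) are one-hot expanded before fitting. Prediction is the majority
#' vote over trees.
#'
#' @param x Data frame / tibble of features (rows = beats).
#' @param y Class labels (character or factor).
#' @param n_trees Number of trees (default 200).
#' @param seed Seed for the forest's bootstrap/feature sampling.
#' @return A `beat_forest` object.
#' @export
train_forest <- function(x, y, n_trees = 200, seed = 1L) {
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("training set must contain >= 2 classes")
  xe <- onehot_expand(as.data.frame(x))
  m <- ncol(xe)
  stopifnot(m >= 1)
  # the backend reads R's RNG stream in addition to its own seed, so
  # the global state is pinned to make training a pure function
  fit <- with_local_rng(as.integer(seed), ranger::ranger(
    x = xe, y = factor(y),
    num.trees = n_trees,
    mtry = max(1L, floor(sqrt(m))),
    splitrule = "gini",
    case.weights = balanced_weights(y),
    seed = as.integer(seed),
    num.threads = 1))
  structure(list(fit = fit, feature_names = names(xe),
                 raw_names = names(as.data.frame(x)),
                 classes = sort(unique(y)), n_trees = n_trees,
                 mtry = max(1L, floor(sqrt(m))), seed = as.integer(seed)),
            class = "beat_forest")
}

onehot_expand <- function(df) {
  out <- list()
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.factor(col) || is.character(col)) {
      col <- as.factor(col)
      for (lev in levels(col)) {
        out[[paste0(nm, "_", lev)]] <- as.numeric(col == lev)
      }
    } else {
      out[[nm]] <- as.numeric(col)
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' @export
predict.beat_forest <- function(object, newdata, ...) {
  xe <- onehot_expand(as.data.frame(newdata))
  missing <- setdiff(object$feature_names, names(xe))
  for (nm in missing) xe[[nm]] <- 0  # unseen factor levels
  xe <- xe[, object$feature_names, drop = FALSE]
  # vote ties are broken through the RNG; pin it for reproducibility
  with_local_rng(object$seed,
                 as.character(stats::predict(object$fit, data = xe,
                                             seed = object$seed,
                                             num.threads = 1)$predictions))
}

#' @export
print.beat_forest <- function(x, ...) {
  cat(sprintf(
    "<beat_forest: %d trees, mtry %d, classes: %s>\n",
    x$n_trees, x$mtry, paste(x$classes, collapse = " ")))
  invisible(x)
}
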