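#' Build the per-sample training set for the read model
#'
#' Training labels come from genomic co-alignment alone: junctional reads
#' *without* any contiguous (N-free) alignment are the positive class (y = 1,
#' likely true spliced alignments) and junctional reads *with* a genomic
#' alignment are the negative class (y = 0, likely artifacts, since a read
#' that also maps contiguously is usually explained by genomic sequence
#' rather than a splice). Genomic co-alignment is not itself a model
#' predictor, so the labels do not leak into the features. Each class is
#' capped at `cap` records, drawn uniformly at random under `seed`.
#'
#' @param features Feature tibble from [extract_features()].
#' @param has_genomic Logical vector, row-aligned with `features`: does the
#'   record's read also have an N-free alignment?
#' @param cap Maximum records per class (default 10000).
#' @param seed Integer seed for the subsampling draw.
#' @return An object of class `training_set`: list with `x` (feature tibble),
#'   `y` (0/1 labels), `n_pos`, `n_neg`, `cap`, `seed`.
#' @export
build_training_set <- function(features, has_genomic, cap = 10000L, seed = 1L) {
  stopifnot(nrow(features) == length(has_genomic))
  pos <- which(!has_genomic)
  neg <- which(has_genomic)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop(sprintf("untrainable sample: %d positive and %d negative junctional reads",
                 length(pos), length(neg)), call. = FALSE)
  }
  withr::with_seed(seed, {
    if (length(pos) > cap) pos <- sort(sample(pos, cap))
    if (length(neg) > cap) neg <- sort(sample(neg, cap))
  })
  idx <- c(pos, neg)
  structure(
    list(x = features[idx, , drop = FALSE],
         y = c(rep(1L, length(pos)), rep(0L, length(neg))),
         index = idx,
         n_pos = length(pos), n_neg = length(neg),
         cap = as.integer(cap), seed = as.integer(seed)),
    class = "training_set"
  )
}

# Design matrix of the read model. Single mode:
#   as_norm + nh + nmm + overlap * max_overlap + softclip_s + entropy
# (the crossing contributes both main effects and their product). Paired mode
# appends the mate's copies of the same terms plus the two fragment
# compatibility indicators.
.model_matrix <- function(features, mode) {
  base_cols <- c("as_norm", "nh", "nmm", "overlap", "max_overlap",
                 "softclip_s", "entropy")
  cols <- base_cols
  if (mode == "paired") {
    cols <- c(cols, paste0("mate_", base_cols),
              "location_compatible", "strand_compatible")
  }
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stop(sprintf("feature vector missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(features[, cols, drop = FALSE])
  m <- cbind(m, overlap_x_max_overlap = m[, "overlap"] * m[, "max_overlap"])
  if (mode == "paired") {
    m <- cbind(m, mate_overlap_x_max_overlap =
                 m[, "mate_overlap"] * m[, "mate_max_overlap"])
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  }
  m
}

#' Fit the penalized logistic read model
#'
#' Fits a lasso-penalized logistic regression (glmnet, alpha = 1) of the
#' training labels on the read features, with the regularization strength
#' chosen by 10-fold cross-validated deviance on seeded fold assignments.
#' Features are centered and scaled on the training set and the
#' standardization is frozen into the model so scoring uses the same
#' transformation.
#'
#' @param training A `training_set` from [build_training_set()].
#' @param mode `"single"` or `"paired"`; selects the predictor set.
#' @param seed Integer seed for the cross-validation fold assignment.
#' @param nfolds Number of cross-validation folds.
#' @return An object of class `read_model`: coefficients (named, including
#'   intercept), the penalty (`alpha`, `lambda`), per-feature center/scale,
#'   `mode` and `seed`.
#' @export
fit_read_model <- function(training, mode = c("single", "paired"), seed = 1L,
                           nfolds = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(training, "training_set"))
  X <- .model_matrix(training$x, mode)
  y <- training$y
  if (length(unique(y)) < 2L) stop("both training classes must be non-empty", call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  if (all(scale == 0)) {
    stop("degenerate design: all features have zero variance", call. = FALSE)
  }
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), length(y))))
  cvfit <- tryCatch(
    glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                      foldid = foldid, standardize = FALSE),
    error = function(e) stop(sprintf("read model failed to converge: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(beta) <- rownames(stats::coef(cvfit, s = "lambda.min"))
  structure(
    list(coefficients = beta,
         penalty = list(alpha = 1, lambda = cvfit$lambda.min, nfolds = nfolds),
         center = center, scale = scale,
         mode = mode, seed = as.integer(seed)),
    class = "read_model"
  )
}

# clip probabilities away from 0/1 so log-odds are finite
.clip_p <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Score junctional reads with a fitted read model
#'
#' Applies the frozen standardization and logistic link to every record's
#' features, yielding `p_hat`, the estimated likelihood that the spliced
#' alignment reflects true expression. Probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` because downstream aggregation works on log-odds.
#'
#' @param model A `read_model` from [fit_read_model()].
#' @param features Feature tibble for all records of the sample.
#' @return Numeric vector of `p_hat`, one per feature row.
#' @export
score_reads <- function(model, features) {
  stopifnot(inherits(model, "read_model"))
  X <- .model_matrix(features, model$mode)
  beta <- model$coefficients[-1]
  X <- X[, names(beta), drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$center[names(beta)]), 2,
              model$scale[names(beta)], "/")
  eta <- drop(model$coefficients[1] + Xs %*% beta)
  .clip_p(stats::plogis(eta))
}

#' Write a read model as a plain-text key/value document
#'
#' @param model A `read_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_read_model <- function(model, path) {
  stopifnot(inherits(model, "read_model"))
  lines <- c(
    sprintf("mode\t%s", model$mode),
    sprintf("seed\t%d", model$seed),
    sprintf("alpha\t%.17g", model$penalty$alpha),
    sprintf("lambda\t%.17g", model$penalty$lambda),
    sprintf("nfolds\t%d", model$penalty$nfolds),
    sprintf("coef\t%s\t%.17g", names(model$coefficients), model$coefficients),
    sprintf("center\t%s\t%.17g", names(model$center), model$center),
    sprintf("scale\t%s\t%.17g", names(model$scale), model$scale)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [write_read_model()]
#'
#' @param path Path to the model text file.
#' @return A `read_model` object.
#' @export
read_read_model <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get1 <- function(key) {
    v <- vapply(parts[vapply(parts, `[[`, "", 1) == key], `[[`, "", 2)
    v[1]
  }
  get_named <- function(key) {
    sel <- parts[vapply(parts, `[[`, "", 1) == key]
    stats::setNames(vapply(sel, function(p) as.numeric(p[[3]]), numeric(1)),
                    vapply(sel, `[[`, "", 2))
  }
  structure(
    list(coefficients = get_named("coef"),
         penalty = list(alpha = as.numeric(get1("alpha")),
                        lambda = as.numeric(get1("lambda")),
                        nfolds = as.integer(get1("nfolds"))),
         center = get_named("center"), scale = get_named("scale"),
         mode = get1("mode"), seed = as.integer(get1("seed"))),
    class = "read_model"
  )
}
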