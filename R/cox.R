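# Negative penalized Breslow log partial likelihood, gradient and Hessian.
# Subjects are processed in decreasing time order with running sums over the
# risk set; ties share the full-risk-set denominator (Breslow).
coxObjective <- function(beta, x, time, event, penalty) {
  ord <- order(time, decreasing = TRUE)
  x <- x[ord, , drop = FALSE]
  time <- time[ord]; event <- event[ord]
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  s0 <- 0; s1 <- numeric(p); s2 <- matrix(0, p, p)
  ll <- 0; g <- numeric(p); H <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1L] == time[i]) j <- j + 1L
    for (k in i:j) {        # add the tied block to the risk set first
      s0 <- s0 + w[k]
      s1 <- s1 + w[k] * x[k, ]
      s2 <- s2 + w[k] * tcrossprod(x[k, ])
    }
    for (k in i:j) {
      if (event[k] == 1) {
        xbar <- s1 / s0
        ll <- ll + eta[k] - log(s0)
        g <- g + x[k, ] - xbar
        H <- H + s2 / s0 - tcrossprod(xbar)
      }
    }
    i <- j + 1L
  }
  list(value = -ll + penalty / 2 * sum(beta^2),
       gradient = -(g - penalty * beta),
       hessian = H + penalty * diag(p))
}

#' Fit a ridge-penalized Cox proportional-hazards model
#'
#' Maximizes the Breslow-tie partial likelihood minus an L2 penalty
#' `(penalty/2) * ||beta||^2` by Newton's method with step halving, converging
#' when the gradient max-norm falls below 1e-7.
#'
#' @param x Numeric matrix of (standardized) covariates.
#' @param time,event Survival outcomes.
#' @param penalty Nonnegative ridge penalty strength.
#' @param center,scale Optional standardization parameters stored in the
#'   model for later raw-table prediction (defaults: identity transform).
#' @return A [CoxModel-class] object.
#' @export
fitCox <- function(x, time, event, penalty = 0, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  if (penalty < 0) stop("penalty must be nonnegative")
  p <- ncol(x)
  beta <- numeric(p)
  obj <- coxObjective(beta, x, time, event, penalty)
  for (it in 1:100) {
    if (max(abs(obj$gradient)) < 1e-7) break
    step <- tryCatch(solve(obj$hessian, -obj$gradient),
                     error = function(e) NULL)
    if (is.null(step))
      stop("Cox fit failed: singular Hessian (try a larger penalty)")
    stepSize <- 1
    repeat {
      cand <- beta + stepSize * step
      candObj <- coxObjective(cand, x, time, event, penalty)
      if (is.finite(candObj$value) && candObj$value <= obj$value + 1e-12)
        break
      stepSize <- stepSize / 2
      if (stepSize < 1e-10)
        stop("Cox fit failed: step halving exhausted (gradient max ",
             format(max(abs(obj$gradient))), ")")
    }
    beta <- cand
    obj <- candObj
  }
  if (max(abs(obj$gradient)) >= 1e-6)
    stop("Cox fit did not converge: gradient max ",
         format(max(abs(obj$gradient))))
  new("CoxModel", features = colnames(x), coefficients = as.numeric(beta),
      penalty = penalty,
      center = if (is.null(center)) setNames(rep(0, p), colnames(x))
               else center[colnames(x)],
      scale = if (is.null(scale)) setNames(rep(1, p), colnames(x))
              else scale[colnames(x)])
}

#' Harrell's concordance index
#'
#' Over comparable pairs (subject i with an event and `time_i < time_j`), the
#' fraction whose risk ordering agrees with the survival ordering
#' (`score_i > score_j` concordant; ties in score count 0.5).
#'
#' @param scores Predicted risk scores (higher = higher hazard).
#' @param time,event Survival outcomes.
#' @return Concordance in [0, 1].
#' @export
cIndex <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; comp <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    if (!any(later)) next
    comp <- comp + sum(later)
    conc <- conc + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# stratified fold assignment by event status
stratifiedFolds <- function(event, folds, seed) {
  assign <- integer(length(event))
  withSeed(seed, {
    for (cl in unique(event)) {
      idx <- which(event == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

# mean/SD of train and validation C-index over folds x repeats for a fixed
# feature set
cvScore <- function(x, time, event, features, penalty, folds, repeats, seed) {
  seeds <- deriveSeeds(seed, repeats)
  trainC <- valC <- numeric()
  for (r in seq_len(repeats)) {
    fold <- stratifiedFolds(event, folds, seeds[r])
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- tryCatch(
        fitCox(x[tr, features, drop = FALSE], time[tr], event[tr], penalty),
        error = function(e) NULL)
      if (is.null(fit)) next
      sTr <- drop(x[tr, features, drop = FALSE] %*% fit@coefficients)
      sVa <- drop(x[!tr, features, drop = FALSE] %*% fit@coefficients)
      trainC <- c(trainC, cIndex(sTr, time[tr], event[tr]))
      valC <- c(valC, tryCatch(cIndex(sVa, time[!tr], event[!tr]),
                               error = function(e) NA_real_))
    }
  }
  c(meanTrainC = mean(trainC), sdTrainC = sd(trainC),
    meanValC = mean(valC, na.rm = TRUE), sdValC = sd(valC, na.rm = TRUE))
}

#' Backward recursive feature elimination for the penalized Cox model
#'
#' Starting from all features, each step scores the current set by stratified
#' `folds`-fold cross-validation repeated `repeats` times (mean validation
#' C-index), then refits the penalized model on the full training set and
#' drops the feature with the smallest absolute coefficient. The optimal set
#' is the step with the highest mean validation C-index (ties favour fewer
#' features).
#'
#' @param x Standardized training matrix.
#' @param time,event Training outcomes.
#' @param folds,repeats Cross-validation layout (defaults 3 x 10).
#' @param seed RNG seed for fold draws.
#' @param penalty Ridge penalty used during elimination.
#' @return list with `trace` (data.frame: step, nFeatures, mean/SD train and
#'   validation C-index, dropped feature) , `stepFeatures` (list of retained
#'   sets per step) and `optimalFeatures`.
#' @export
rfeCox <- function(x, time, event, folds = 3L, repeats = 10L, seed = 1L,
                   penalty = 0.1) {
  stopifnot(ncol(x) >= 1)
  current <- colnames(x)
  seeds <- deriveSeeds(seed, ncol(x))
  rows <- list(); stepFeatures <- list()
  step <- 0L
  while (length(current) >= 1L) {
    step <- step + 1L
    sc <- cvScore(x, time, event, current, penalty, folds, repeats,
                  seeds[step])
    stepFeatures[[step]] <- current
    dropped <- NA_character_
    if (length(current) > 1L) {
      fit <- fitCox(x[, current, drop = FALSE], time, event, penalty)
      dropped <- current[which.min(abs(fit@coefficients))]
    }
    rows[[step]] <- data.frame(step = step, nFeatures = length(current),
                               meanTrainC = sc["meanTrainC"],
                               sdTrainC = sc["sdTrainC"],
                               meanValC = sc["meanValC"],
                               sdValC = sc["sdValC"],
                               dropped = dropped)
    if (length(current) == 1L) break
    current <- setdiff(current, dropped)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  best <- which(trace$meanValC == max(trace$meanValC, na.rm = TRUE))
  best <- best[which.min(trace$nFeatures[best])]
  list(trace = trace, stepFeatures = stepFeatures,
       optimalFeatures = stepFeatures[[best]], optimalStep = best)
}

#' Tune the ridge penalty by cross-validated C-index
#'
#' Grid search over a log-spaced penalty grid with stratified `folds`-fold
#' cross-validation; returns the penalty maximizing the mean validation
#' C-index (ties favour the larger penalty).
#'
#' @param x Standardized training matrix.
#' @param time,event Training outcomes.
#' @param features Feature subset to model.
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @param grid Penalty grid (default `10^seq(-3, 2, length.out = 21)`).
#' @return list with `penalty` and the per-grid `cv` data.frame.
#' @export
tunePenalty <- function(x, time, event, features = colnames(x), folds = 5L,
                        seed = 1L, grid = 10^seq(-3, 2, length.out = 21)) {
  stopifnot(length(features) >= 1)
  grid <- sort(grid)
  scores <- vapply(grid, function(lam)
    cvScore(x, time, event, features, lam, folds, 1L, seed)["meanValC"], 0)
  best <- which(scores >= max(scores, na.rm = TRUE) - 1e-12)
  best <- max(best)  # ties -> larger penalty
  list(penalty = grid[best],
       cv = data.frame(penalty = grid, meanValC = as.numeric(scores)))
}

#' Predict linear risk scores
#'
#' Applies the model's stored standardization parameters to a raw feature
#' table and returns the linear predictor `x^T beta` (higher = higher
#' hazard). A subject at the training feature means scores 0.
#'
#' @param model A [CoxModel-class].
#' @param table Raw feature matrix containing the model's features.
#' @return Named numeric vector of risk scores.
#' @export
predictRisk <- function(model, table) {
  if (is.null(dim(table))) table <- matrix(table, nrow = 1,
                                           dimnames = list(NULL, names(table)))
  missing <- setdiff(model@features, colnames(table))
  if (length(missing))
    stopf("table lacks model feature(s): %s", paste(missing, collapse = ", "))
  x <- table[, model@features, drop = FALSE]
  z <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  drop(z %*% model@coefficients)
}
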