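# CoMFA-style PLS model: NIPALS PLS1 on the pretreated, block-weighted
# field matrix, with leave-one-out cross-validation, field-combination
# model selection, external test statistics and coefficient contour
# export.  comfa_pls() is the central fitting function; the usual
# modelling methods (print, summary, coef, predict, fitted, residuals,
# plot, simulate) operate on the returned object.

# -- NIPALS PLS1 core ------------------------------------------------

# X: n x p (uncentered), y: length n.  Returns weights W, loadings P,
# y-loadings q, scores T, regression vector in centered-X space, means.
nipals_pls1 <- function(X, y, nc) {
  n <- nrow(X); p <- ncol(X)
  if (nc < 1L) stop("at least one component is required")
  if (nc > min(n - 1L, p))
    stop("nc = ", nc, " exceeds min(rows - 1, columns) = ", min(n - 1L, p))
  if (stats::sd(y) == 0) stop("constant response: nothing to model")
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- matrix(0, p, nc); P <- matrix(0, p, nc)
  Tm <- matrix(0, n, nc); q <- numeric(nc)
  used <- 0L
  for (a in seq_len(nc)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
    used <- a
  }
  if (used == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Tm <- Tm[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  beta <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, q = q, scores = Tm, beta = drop(beta),
       x_mean = xm, y_mean = ym, ncomp = used)
}

# -- preparation state (pretreatment + BUW frozen from training) -----

.make_prep <- function(fm, fields) {
  keep <- fm$block %in% fields
  list(fields = fields,
       cap = fm$treatment$cap, zero_threshold = fm$treatment$zero_threshold,
       cols = which(keep & fm$alive),
       block = fm$block, node = fm$node, grid = fm$grid,
       buw_w = fm$buw_w)
}

# Apply frozen pretreatment + BUW to a raw field matrix (same grid and
# field layout), returning the prepared X restricted to alive columns.
.apply_prep <- function(prep, fm_raw) {
  if (!identical(fm_raw$grid$dims, prep$grid$dims) ||
      max(abs(fm_raw$grid$origin - prep$grid$origin)) > 1e-6)
    stop("newdata fields were computed on a different grid")
  X <- fm_raw$X
  if (!fm_raw$treatment$pretreated) {
    X[X > prep$cap] <- prep$cap
    neg <- fm_raw$block[col(X)] == "electrostatic" & X < -prep$cap
    X[neg] <- -prep$cap
    X[abs(X) < prep$zero_threshold] <- 0
  }
  if (!fm_raw$treatment$buw && !is.null(prep$buw_w)) {
    for (b in names(prep$buw_w))
      X[, fm_raw$block == b] <- X[, fm_raw$block == b, drop = FALSE] *
        prep$buw_w[b]
  }
  X[, prep$cols, drop = FALSE]
}

# -- fitting ---------------------------------------------------------

#' Fit a CoMFA-style PLS model on a field matrix
#'
#' Restricts the field matrix to the requested field blocks (and, when
#' given, the training rows), applies pretreatment and Block Unscaled
#' Weighting unless already applied, optionally groups variables by
#' Smart Region Definition using a pilot fit, and fits a NIPALS PLS1
#' model of pKi on the surviving variables.
#'
#' @param fm A [compute_fields()] matrix (raw or already pretreated).
#' @param y Response vector (pKi), one value per row of `fm$X`.
#' @param ncomp Number of PLS components.
#' @param fields Field blocks to use, subset of the blocks in `fm`.
#' @param rows Optional integer/logical selection of training rows.
#' @param srd Apply Smart Region Definition grouping (default `FALSE`).
#' @param cap,zero_threshold,nlevel_max Pretreatment parameters, used
#'   only when `fm` is raw (see [pretreat()]).
#' @param srd_args List of arguments for [srd_group()].
#' @return Object of class `comfa_pls` with (among others) `coef` on the
#'   prepared-variable scale, `fitted`, `residuals`, `r2`, `s`
#'   (fitting SD with `n - ncomp - 1` denominator), and the frozen
#'   preparation state used by [predict.comfa_pls()] and [loo_q2()].
#' @seealso [select_model()] for scanning field combinations and
#'   component counts, [loo_q2()] for cross-validation,
#'   [export_contours()] for coefficient maps.
#' @export
comfa_pls <- function(fm, y, ncomp, fields = unique(fm$block),
                      rows = NULL, srd = FALSE,
                      cap = 30, zero_threshold = 0.05, nlevel_max = 4L,
                      srd_args = list()) {
  stopifnot(inherits(fm, "field_matrix"))
  fields <- match.arg(fields, unique(fm$block), several.ok = TRUE)
  if (!is.null(rows)) fm <- subset_rows(fm, rows)
  if (length(y) != nrow(fm$X))
    stop("length(y) must match the number of (selected) compounds")
  if (!fm$treatment$pretreated)
    fm <- pretreat(fm, cap = cap, zero_threshold = zero_threshold,
                   nlevel_max = nlevel_max)
  if (!fm$treatment$buw) fm <- buw_scale(fm)
  if (srd) {
    prep0 <- .make_prep(fm, fields)
    X0 <- fm$X[, prep0$cols, drop = FALSE]
    nc0 <- min(ncomp, nrow(X0) - 1L, ncol(X0))
    pilot <- nipals_pls1(X0, y, nc0)
    w <- numeric(ncol(fm$X))
    w[prep0$cols] <- abs(pilot$beta)
    fm <- do.call(srd_group, c(list(fm, weights = w), srd_args))
  }
  prep <- .make_prep(fm, fields)
  if (length(prep$cols) == 0L)
    stop("no alive variables left in the requested field blocks")
  Xp <- fm$X[, prep$cols, drop = FALSE]
  fit <- nipals_pls1(Xp, y, ncomp)
  fitted <- drop(sweep(Xp, 2, fit$x_mean) %*% fit$beta) + fit$y_mean
  res <- y - fitted
  n <- length(y)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  s <- sqrt(sum(res^2) / max(n - fit$ncomp - 1L, 1L))
  structure(list(call = match.call(), ncomp = fit$ncomp, fields = fields,
                 prep = prep, pls = fit, Xp = Xp, y = y,
                 ids = rownames(fm$X),
                 fitted = fitted, residuals = res, r2 = r2, s = s),
            class = "comfa_pls")
}

#' @export
print.comfa_pls <- function(x, ...) {
  cat("CoMFA-style PLS model (", paste(x$fields, collapse = " + "), ")\n",
      sep = "")
  cat("  compounds:", length(x$y), "  variables:", length(x$prep$cols),
      "  components:", x$ncomp, "\n")
  cat(sprintf("  R2 = %.3f  S = %.3f\n", x$r2, x$s))
  invisible(x)
}

#' @export
coef.comfa_pls <- function(object, ...) {
  b <- numeric(length(object$prep$block))
  b[object$prep$cols] <- object$pls$beta
  names(b) <- paste0(substr(object$prep$block, 1, 1), object$prep$node)
  b
}

#' @export
fitted.comfa_pls <- function(object, ...) object$fitted

#' @export
residuals.comfa_pls <- function(object, ...) object$residuals

#' Predict pKi for new compounds
#'
#' @param object A [comfa_pls()] model.
#' @param newdata A raw `field_matrix` computed on the model's grid (or
#'   omitted for fitted values).
#' @param rows Optional row selection of `newdata`.
#' @param ... Unused.
#' @return Predicted response vector.
#' @export
predict.comfa_pls <- function(object, newdata = NULL, rows = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stopifnot(inherits(newdata, "field_matrix"))
  if (!is.null(rows)) newdata <- subset_rows(newdata, rows)
  Xp <- .apply_prep(object$prep, newdata)
  drop(sweep(Xp, 2, object$pls$x_mean) %*% object$pls$beta) +
    object$pls$y_mean
}

#' @export
summary.comfa_pls <- function(object, loo = TRUE, ...) {
  cv <- if (loo) loo_q2(object) else NULL
  out <- list(model = object, q2 = cv$q2, s_loo = cv$s_loo,
              contributions = field_contributions(object))
  class(out) <- "summary.comfa_pls"
  out
}

#' @export
print.summary.comfa_pls <- function(x, ...) {
  print(x$model)
  if (!is.null(x$q2))
    cat(sprintf("  Q2 (LOO) = %.3f  S_LOO = %.3f\n", x$q2, x$s_loo))
  cat("  field contributions:",
      paste(sprintf("%s %.2f", names(x$contributions), x$contributions),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.comfa_pls <- function(x, loo = FALSE, ...) {
  yhat <- x$fitted
  graphics::plot(x$y, yhat, xlab = "experimental pKi",
                 ylab = "predicted pKi",
                 main = paste("CoMFA-style PLS (",
                              paste(x$fields, collapse = "+"), ")"), ...)
  graphics::abline(0, 1, lty = 2)
  if (loo) {
    cv <- loo_q2(x)
    graphics::points(x$y, cv$predictions, pch = 1, col = "grey40")
  }
  invisible(x)
}

#' @export
simulate.comfa_pls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$y)
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(n, 0, object$s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# -- cross-validation ------------------------------------------------

#' Leave-one-out cross-validation
#'
#' Refits the model once per training compound on the remaining rows
#' (re-centering each time) and predicts the left-out compound.  The
#' pretreatment, block weights and alive-variable set are frozen from
#' the full training matrix, as in standard field-QSAR practice.
#' `Q2 = 1 - PRESS / sum((y - mean(y))^2)`, `S_LOO = sqrt(PRESS / n)`.
#'
#' @param model A [comfa_pls()] model.
#' @return List with `q2`, `s_loo` and per-compound `predictions`.
#' @export
loo_q2 <- function(model) {
  stopifnot(inherits(model, "comfa_pls"))
  X <- model$Xp; y <- model$y
  n <- length(y)
  if (n < 3L) stop("leave-one-out needs at least 3 training rows")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    nc_i <- min(model$ncomp, n - 2L, ncol(X))
    f <- nipals_pls1(X[-i, , drop = FALSE], y[-i], nc_i)
    pred[i] <- drop((X[i, ] - f$x_mean) %*% f$beta) + f$y_mean
  }
  press <- sum((y - pred)^2)
  list(q2 = 1 - press / sum((y - mean(y))^2),
       s_loo = sqrt(press / n),
       predictions = pred)
}

# -- model selection and reporting -----------------------------------

#' Select the best field combination and component count
#'
#' Fits candidate models over the requested field sets and component
#' range and returns the one with the highest leave-one-out `Q2`; ties
#' are broken by fewer components, then fewer fields.
#'
#' @param fm A `field_matrix` holding all candidate blocks.
#' @param y Response for the training rows.
#' @param rows Optional training-row selection.
#' @param field_sets Named list of field combinations to try; default
#'   `S`, `E` and `SE`.
#' @param ncomp_max Largest component count scanned (default 8).
#' @param ... Passed to [comfa_pls()].
#' @return List with `model` (the winning `comfa_pls`), `q2`, `s_loo`,
#'   and `scan`, a data.frame of all candidates.
#' @export
select_model <- function(fm, y, rows = NULL,
                         field_sets = list(S = "steric",
                                           E = "electrostatic",
                                           SE = c("steric",
                                                  "electrostatic")),
                         ncomp_max = 8L, ...) {
  scan <- list(); best <- NULL
  for (fs in names(field_sets)) {
    for (nc in seq_len(ncomp_max)) {
      cand <- tryCatch(
        comfa_pls(fm, y, ncomp = nc, fields = field_sets[[fs]],
                  rows = rows, ...),
        error = function(e) NULL)
      if (is.null(cand) || cand$ncomp < nc) next
      cv <- loo_q2(cand)
      scan[[length(scan) + 1L]] <- data.frame(
        fields = fs, ncomp = nc, r2 = cand$r2, s = cand$s,
        q2 = cv$q2, s_loo = cv$s_loo)
      better <- is.null(best) || cv$q2 > best$q2 + 1e-12 ||
        (abs(cv$q2 - best$q2) <= 1e-12 &&
           (nc < best$model$ncomp ||
              (nc == best$model$ncomp &&
                 length(field_sets[[fs]]) < length(best$model$fields))))
      if (better) best <- list(model = cand, q2 = cv$q2,
                               s_loo = cv$s_loo, cv = cv)
    }
  }
  if (is.null(best)) stop("no candidate model could be fitted")
  best$scan <- do.call(rbind, scan)
  best
}

#' External test-set statistics
#'
#' `Rtest2` is the squared Pearson correlation between predicted and
#' observed activities; `S_test = sqrt(sum((pred - obs)^2) / n_test)`.
#'
#' @param observed,predicted Activity vectors over the test compounds
#'   (at least 2).
#' @return Named vector `c(rtest2 = , s_test = )`.
#' @export
external_stats <- function(observed, predicted) {
  if (length(observed) < 2L || length(observed) != length(predicted))
    stop("need >= 2 matched (observed, predicted) pairs")
  if (stats::sd(observed) == 0)
    stop("constant observed vector: correlation undefined")
  c(rtest2 = stats::cor(observed, predicted)^2,
    s_test = sqrt(mean((predicted - observed)^2)))
}

#' Relative field-block contributions
#'
#' Per component the share of modelled response variance is
#' `q_a^2 ||t_a||^2` (normalised over components); the squared PLS
#' weights of component `a` (unit length) split that share over
#' variables.  A block's contribution is the weight-squared mass it
#' carries, summed over components with those shares -- contributions
#' over blocks sum to 1.
#'
#' @param model A [comfa_pls()] model.
#' @return Named numeric vector over the model's field blocks.
#' @export
field_contributions <- function(model) {
  stopifnot(inherits(model, "comfa_pls"))
  blocks <- unique(model$fields)
  if (length(blocks) == 1L)
    return(stats::setNames(1, blocks))
  colblock <- model$prep$block[model$prep$cols]
  share <- model$pls$q^2 * colSums(model$pls$scores^2)
  share <- share / sum(share)
  out <- vapply(blocks, function(b) {
    sum(vapply(seq_len(model$ncomp), function(a) {
      share[a] * sum(model$pls$W[colblock == b, a]^2)
    }, numeric(1)))
  }, numeric(1))
  out / sum(out)
}

#' Export coefficient contour maps
#'
#' For each field block, writes the per-node map
#' `coefficient x training-column standard deviation` (the usual
#' "stdev*coeff" CoMFA display) as an OpenDX file, with dead variables
#' at zero.  Positive/negative iso-levels are reported at plus/minus
#' the `percentile` quantile of the nonzero absolute map values.
#'
#' @param model A [comfa_pls()] model.
#' @param dir Output directory (created if needed).
#' @param percentile Iso-level quantile (default 0.85).
#' @return Invisibly, a list per field with `path`, `iso` and `values`.
#' @export
export_contours <- function(model, dir, percentile = 0.85) {
  stopifnot(inherits(model, "comfa_pls"))
  if (is.null(model$prep$grid)) stop("model carries no grid metadata")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sds <- apply(model$Xp, 2, stats::sd)
  full <- numeric(length(model$prep$block))
  full[model$prep$cols] <- model$pls$beta * sds
  out <- list()
  for (b in model$fields) {
    v <- full[model$prep$block == b]
    # order by node index so v[node] is the map
    v <- v[order(model$prep$node[model$prep$block == b])]
    path <- file.path(dir, paste0("coeff_", b, ".dx"))
    write_dx(v, model$prep$grid, path)
    nz <- abs(v[v != 0])
    iso <- if (length(nz)) stats::quantile(nz, percentile, names = FALSE)
      else 0
    out[[b]] <- list(path = path, iso = c(-iso, iso), values = v)
  }
  invisible(out)
}
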