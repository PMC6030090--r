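#' Multiple linear regression with intercept
#'
#' The inner least-squares evaluator of the subset search. Rank-deficient
#' design matrices (e.g. duplicated columns) trigger a degeneracy warning;
#' aliased coefficients are reported as 0 and the residual sum of squares
#' equals the fit on the independent columns.
#'
#' @param X numeric feature matrix (no intercept column).
#' @param y response vector, `length(y) > ncol(X)`.
#' @return list with `coefficients` (intercept first), `rss`, `r2`, `rmse`.
#' @export
olsMulti <- function(X, y) {
    X <- as.matrix(X)
    n <- length(y)
    if (n <= ncol(X))
        stop("need more observations than features (n = ", n, ", p = ",
             ncol(X), ")", call. = FALSE)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("V", seq_len(ncol(X)))
    qx <- qr(cbind(`(Intercept)` = 1, X))
    if (qx$rank < ncol(X) + 1L)
        warning("degenerate design: ", ncol(X) + 1L - qx$rank,
                " linearly dependent column(s)", call. = FALSE)
    cf <- qr.coef(qx, y)
    cf[is.na(cf)] <- 0
    res <- qr.resid(qx, y)
    rss <- sum(res^2)
    sst <- sum((y - mean(y))^2)
    list(coefficients = cf, rss = rss,
         r2 = if (sst > 0) 1 - rss / sst else NA_real_,
         rmse = sqrt(rss / n))
}

## Fast RSS evaluator over subsets: centered Gram matrices + Cholesky,
## QR fallback for singular subsets. Returns a closure; $count() gives the
## number of evaluations performed.
.makeRSSEvaluator <- function(X, y) {
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    G <- crossprod(Xc)
    cvec <- drop(crossprod(Xc, yc))
    tss <- sum(yc^2)
    count <- 0L
    evaluate <- function(idx) {
        count <<- count + 1L
        if (length(idx) == 0L) return(tss)
        rss <- tryCatch({
            R <- chol(G[idx, idx, drop = FALSE])
            tss - sum(backsolve(R, cvec[idx], transpose = TRUE)^2)
        }, error = function(e) {
            sum(qr.resid(qr(Xc[, idx, drop = FALSE]), yc)^2)
        })
        max(rss, 0)
    }
    list(evaluate = evaluate, count = function() count, tss = tss)
}

#' Exact best-subset selection by branch and bound
#'
#' Finds the size-`k` feature subset with globally minimal residual sum of
#' squares (equivalently maximal R²) among all `choose(p, k)` subsets --
#' exact optimality, not a heuristic. The search exploits the monotonicity of
#' RSS under variable addition: the RSS of the model on a node's chosen plus
#' remaining candidate features lower-bounds the RSS of every size-k subset in
#' that subtree, so subtrees whose bound cannot beat the incumbent are pruned
#' without enumeration. A greedy forward pass seeds the incumbent and
#' candidates are ordered by marginal explanatory power so pruning bites
#' early. Equal-RSS ties (within 1e-9) resolve lexicographically by candidate
#' index, making the output deterministic. The intercept is always included
#' and never selectable.
#'
#' @param X numeric feature matrix with named columns (the candidates).
#' @param y response vector; `length(y) > k + 1`.
#' @param k subset size, `1 <= k <= ncol(X)`.
#' @return a [SubsetResult-class].
#' @examples
#' set.seed(42)
#' X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
#' y <- 1 + 2 * X[, 2] - X[, 5] + rnorm(50, sd = 0.01)
#' members(branchAndBound(X, y, 2))
#' @export
branchAndBound <- function(X, y, k) {
    X <- as.matrix(X)
    p <- ncol(X)
    n <- length(y)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
    if (k < 1 || k > p) stop("k must be in 1..", p, call. = FALSE)
    if (n <= k + 1L)
        stop("need n > k + 1 observations", call. = FALSE)
    ev <- .makeRSSEvaluator(X, y)
    tieTol <- 1e-9

    ## candidate order: strongest single features first (better incumbents)
    single <- vapply(seq_len(p), function(j) ev$evaluate(j), numeric(1))
    ord <- order(single)

    ## greedy forward incumbent
    chosen <- integer(0)
    avail <- ord
    for (step in seq_len(k)) {
        rs <- vapply(avail, function(j) ev$evaluate(c(chosen, j)), numeric(1))
        pick <- avail[which.min(rs)]
        chosen <- c(chosen, pick)
        avail <- setdiff(avail, pick)
    }
    best <- list(rss = ev$evaluate(chosen), idx = sort(chosen))

    recurse <- function(sel, cand) {
        nsel <- length(sel)
        if (nsel == k) {
            rss <- ev$evaluate(sel)
            sidx <- sort(sel)
            if (rss < best$rss - tieTol ||
                (abs(rss - best$rss) <= tieTol &&
                 .lexLess(sidx, best$idx)))
                best <<- list(rss = rss, idx = sidx)
            return(invisible())
        }
        if (nsel + length(cand) < k) return(invisible())
        bound <- ev$evaluate(c(sel, cand))
        if (bound > best$rss + tieTol) return(invisible())
        v <- cand[1]
        rest <- cand[-1]
        recurse(c(sel, v), rest)       # include v
        recurse(sel, rest)             # exclude v
        invisible()
    }
    recurse(integer(0), ord)

    fit <- olsMulti(X[, best$idx, drop = FALSE], y)
    res <- methods::new("SubsetResult", k = as.integer(k),
                        members = colnames(X)[best$idx],
                        coefficients = fit$coefficients, rss = fit$rss,
                        r2 = fit$r2, rmse = fit$rmse, n = as.integer(n))
    attr(res, "nodesExplored") <- ev$count()
    res
}

.lexLess <- function(a, b) {
    for (i in seq_along(a)) {
        if (a[i] < b[i]) return(TRUE)
        if (a[i] > b[i]) return(FALSE)
    }
    FALSE
}

#' Exhaustive best-subset search
#'
#' Full enumeration of all `choose(p, k)` subsets; provided as the
#' independent optimality check for [branchAndBound()] at small `p`
#' (`p <= 20`).
#'
#' @inheritParams branchAndBound
#' @return a [SubsetResult-class].
#' @export
exhaustiveSearch <- function(X, y, k) {
    X <- as.matrix(X)
    p <- ncol(X)
    if (p > 20) stop("exhaustive search limited to p <= 20", call. = FALSE)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
    if (k < 1 || k > p) stop("k must be in 1..", p, call. = FALSE)
    ev <- .makeRSSEvaluator(X, y)
    combos <- combn(p, k)
    rs <- apply(combos, 2, ev$evaluate)
    bestRSS <- min(rs)
    ties <- which(rs <= bestRSS + 1e-9)
    bestCol <- ties[1]
    for (j in ties[-1])
        if (.lexLess(combos[, j], combos[, bestCol])) bestCol <- j
    idx <- combos[, bestCol]
    fit <- olsMulti(X[, idx, drop = FALSE], y)
    methods::new("SubsetResult", k = as.integer(k),
                 members = colnames(X)[idx],
                 coefficients = fit$coefficients, rss = fit$rss,
                 r2 = fit$r2, rmse = fit$rmse, n = as.integer(length(y)))
}

#' Optimal-subset path over increasing subset sizes
#'
#' Runs [branchAndBound()] for `k = 1 ... kMax`. Because the size-(k+1)
#' optimum can always embed the size-k optimum, RSS is non-increasing and R²
#' non-decreasing along the path; this is verified and enforced as an
#' internal consistency check.
#'
#' @inheritParams branchAndBound
#' @param kMax largest subset size, `<= ncol(X)`.
#' @return a [SubsetPath-class].
#' @export
subsetPath <- function(X, y, kMax) {
    X <- as.matrix(X)
    p <- ncol(X)
    if (kMax < 1 || kMax > p) stop("kMax must be in 1..", p, call. = FALSE)
    results <- vector("list", kMax)
    nodes <- 0
    for (k in seq_len(kMax)) {
        results[[k]] <- branchAndBound(X, y, k)
        nodes <- nodes + attr(results[[k]], "nodesExplored")
    }
    rss <- vapply(results, function(r) r@rss, numeric(1))
    if (any(diff(rss) > 1e-8 * max(rss[1], 1)))
        stop("internal error: RSS increased along the subset path",
             call. = FALSE)
    methods::new("SubsetPath", results = results, nodesExplored = nodes,
                 exhaustiveNodes = sum(choose(p, seq_len(kMax))))
}

#' Smallest subset size where the fit stabilizes
#'
#' Returns the smallest `k >= 2` whose R² gain over `k - 1` falls below
#' `threshold` (the path's point of diminishing returns); `kMax` if the gain
#' never falls below it.
#'
#' @param path a [SubsetPath-class].
#' @param threshold R² gain threshold (default 0.01).
#' @return integer subset size.
#' @export
stableK <- function(path, threshold = 0.01) {
    r2s <- vapply(path@results, function(r) r@r2, numeric(1))
    if (length(r2s) == 1L) return(1L)
    gains <- diff(r2s)
    hit <- which(gains < threshold)
    if (length(hit)) hit[1] + 1L else length(r2s)
}

#' Apply a fitted subset model to a feature table
#'
#' Predicts C/N from the stored coefficients and evaluates the predictions
#' against the observed C/N of the target table. The evaluation R² is
#' `1 - SSE/SST` on the target table and may be negative out of domain; a
#' not-significant flag (p >= 0.01 for the predicted-observed association)
#' reproduces the dash convention of cross-application reports.
#'
#' @param result a [SubsetResult-class].
#' @param table `data.frame` containing all member columns and `CN`.
#' @param response name of the observed response column (default `"CN"`).
#' @return list with `predictions`, `r2`, `rmse`, `p`, `significant`.
#' @export
applyModel <- function(result, table, response = "CN") {
    stopifnot(methods::is(result, "SubsetResult"))
    missing <- setdiff(result@members, colnames(table))
    if (length(missing))
        stop("feature table lacks member column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    Xs <- as.matrix(table[, result@members, drop = FALSE])
    pred <- drop(result@coefficients[1] + Xs %*% result@coefficients[-1])
    obs <- table[[response]]
    sse <- sum((obs - pred)^2)
    sst <- sum((obs - mean(obs))^2)
    n <- length(obs)
    rho <- suppressWarnings(cor(pred, obs))
    p <- if (is.finite(rho) && abs(rho) < 1) {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tstat), df = n - 2)
    } else if (is.finite(rho)) 0 else NA_real_
    list(predictions = pred,
         r2 = if (sst > 0) 1 - sse / sst else NA_real_,
         rmse = sqrt(sse / n), p = p,
         significant = is.finite(p) && p < 0.01)
}
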