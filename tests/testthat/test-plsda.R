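test_that("one-variable PLS equals univariate least squares", {
    set.seed(31)
    x <- matrix(rnorm(14), 14, 1)
    y <- rep(c(0, 1), 7)
    m <- fitPLSDA(x, y, ncomp = 1, autoscale = FALSE)
    ols <- lm(y ~ x)
    expect_equal(unname(m@fitted), unname(fitted(ols)),
                 tolerance = 1e-10)
    expect_equal(unname(coef(m)), unname(coef(ols)[2]),
                 tolerance = 1e-10)
})

test_that("full-component PLS fitted values match multiple regression", {
    set.seed(32)
    for (rep in 1:50) {
        n <- sample(10:20, 1)
        p <- sample(2:8, 1)
        X <- matrix(rnorm(n * p), n, p)
        y <- rep_len(c(0, 1), n)
        m <- fitPLSDA(X, y, ncomp = p)
        ols <- lm(y ~ X)
        expect_equal(unname(m@fitted), unname(fitted(ols)),
                     tolerance = 1e-8)
    }
})

test_that("score vectors are orthogonal and b-collapse matches LV prediction", {
    set.seed(33)
    X <- matrix(rnorm(30 * 12), 30, 12)
    y <- rep(c("C", "T"), 15)
    m <- fitPLSDA(X, y, ncomp = 4)
    G <- crossprod(m@scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
    ## prediction through the latent-variable route (scores x yloadings)
    ## equals prediction through the collapsed coefficient vector
    Xs <- sweep(sweep(X, 2, m@center), 2, m@scale, `/`)
    Xd <- sweep(Xs, 2, colMeans(Xs))
    ## recompute scores of training data from weights via R = W (P'W)^-1
    R <- m@weights %*% solve(crossprod(m@loadings, m@weights))
    Tnew <- Xd %*% R
    lvPred <- mean(m@y) + drop(Tnew %*% m@yloadings)
    expect_equal(lvPred, unname(m@fitted), tolerance = 1e-10)
})

test_that("prediction is consistent, tie-breaks to treated, and is
           invariant to joint column permutation", {
    set.seed(34)
    X <- matrix(rnorm(20 * 6), 20, 6)
    y <- rep(c("C", "T"), 10)
    m <- fitPLSDA(X, y, ncomp = 3)
    pr <- predict(m, X)
    expect_equal(pr$response, unname(m@fitted), tolerance = 1e-12)
    ## response exactly at the threshold is classified treated
    m2 <- m
    m2@intercept <- m@intercept + (0.5 - pr$response[1])
    expect_equal(predict(m2, X)$class[1], "T")
    ## joint permutation of columns and model bookkeeping
    perm <- sample(6)
    m3 <- fitPLSDA(X[, perm], y, ncomp = 3)
    expect_equal(predict(m3, X[, perm])$response, pr$response,
                 tolerance = 1e-10)
    expect_error(predict(m, X[, 1:5]), "columns")
})

test_that("separable one-dimensional classes are perfectly classified", {
    x <- matrix(c(rnorm(8, -3), rnorm(8, 3)), 16, 1)
    y <- rep(c("C", "T"), each = 8)
    m <- fitPLSDA(x, y, ncomp = 1)
    expect_equal(
        classificationMetrics(y, predict(m, x)$class)$accuracy, 100)
})

test_that("VIP scores satisfy the mean-square identity and concentration", {
    set.seed(35)
    for (rep in 1:100) {
        n <- sample(8:16, 1)
        p <- sample(3:10, 1)
        X <- matrix(rnorm(n * p), n, p)
        y <- rep_len(c(0, 1), n)
        A <- sample(seq_len(min(n - 2, p)), 1)
        v <- vipScores(fitPLSDA(X, y, ncomp = A))
        expect_lt(abs(mean(v^2) - 1), 1e-10)
        expect_true(all(v >= 0))
    }
    ## single informative variable (weight vector = e1): VIP1 = sqrt(p),
    ## the rest 0. Noise columns are centred within each class so their
    ## covariance with the response is exactly zero.
    p <- 6L
    y <- rep(c(0, 1), each = 6)
    noise <- matrix(rnorm(12 * (p - 1)), 12)
    noise <- noise - apply(noise, 2, ave, y)
    X <- cbind(rep(c(-1, 1), each = 6), noise)
    v <- vipScores(fitPLSDA(X, y, ncomp = 1))
    expect_equal(unname(v[1]), sqrt(p), tolerance = 1e-10)
    expect_equal(unname(v[-1]), rep(0, p - 1), tolerance = 1e-10)
    ## equal weights on all variables: every VIP equals 1
    Xeq <- matrix(rep(rep(c(-1, 1), each = 6), p), 12, p) +
        matrix(rnorm(12 * p, sd = 1e-6), 12)
    veq <- vipScores(fitPLSDA(Xeq, y, ncomp = 1))
    expect_equal(unname(veq), rep(1, p), tolerance = 1e-3)
})

test_that("VIP scores match the mixOmics oracle", {
    skip_if_not_installed("mixOmics")
    set.seed(36)
    X <- matrix(rnorm(24 * 10), 24, 10)
    y <- rep(c(0, 1), 12)
    for (A in c(1L, 3L)) {
        m <- fitPLSDA(X, y, ncomp = A)
        ref <- mixOmics::pls(scale(X), y, ncomp = A, scale = FALSE,
                             mode = "regression")
        vref <- mixOmics::vip(ref)[, A]
        expect_equal(unname(vipScores(m)), unname(vref),
                     tolerance = 1e-6)
    }
})

test_that("accuracy and non-error rate follow their definitions", {
    y <- rep(c("C", "T"), each = 18)
    expect_equal(classificationMetrics(y, y),
                 list(accuracy = 100, ner = 100,
                      confusion = table(factor(y, c("C", "T")),
                                        factor(y, c("C", "T")))),
                 ignore_attr = TRUE)
    ## 35 of 36 correct, one error in one class of 18
    pred <- y; pred[1] <- "T"
    m <- classificationMetrics(y, pred)
    expect_equal(m$accuracy, 100 * 35 / 36)
    expect_equal(round(m$accuracy, 2), 97.22)
    expect_equal(m$ner, 100 * (17 / 18 + 1) / 2)
    ## all predicted one class on balanced data
    m2 <- classificationMetrics(y, rep("T", 36))
    expect_equal(m2$accuracy, 50)
    expect_equal(m2$ner, 50)
    ## unbalanced classes: accuracy and NER diverge
    y3 <- c(rep("C", 9), rep("T", 3))
    m3 <- classificationMetrics(y3, rep("C", 12))
    expect_equal(m3$accuracy, 75)
    expect_equal(m3$ner, 50)
    expect_error(classificationMetrics(y3, y3[-1]), "length")
    expect_error(classificationMetrics(y, c(rep("C", 35), "Z")),
                 "unknown label")
})

test_that("degenerate fits are rejected with clear errors", {
    X <- matrix(rnorm(20), 10, 2)
    expect_error(fitPLSDA(X, rep("C", 10), ncomp = 1), "two classes")
    expect_error(fitPLSDA(X, rep(c("C", "T"), 5), ncomp = 5), "ncomp")
    Xc <- X; Xc[, 2] <- 7
    expect_error(fitPLSDA(Xc, rep(c("C", "T"), 5), ncomp = 1),
                 "constant")
})
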