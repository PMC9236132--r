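test_that("the CFS merit reduces to known closed forms", {
  expect_equal(emodyn:::cfs_merit(0.6, 0), 0.6)
  expect_equal(emodyn:::cfs_merit(c(0.5, 0.5), 0), 2 * 0.5 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(emodyn:::cfs_merit(c(0.5, 0.5), 0), 0.7071, tolerance = 1e-4)
})

test_that("a feature equal to the label is selected first", {
  set.seed(1)
  y <- rep(c(0, 1), each = 25)
  X <- cbind(noise1 = rnorm(50), label_copy = y, noise2 = rnorm(50),
             weak = y + rnorm(50, sd = 2))
  sel <- cfs_select(X, y, n_select = 2)
  expect_equal(sel[1], "label_copy")
})

test_that("redundant copies of a good feature are penalised", {
  set.seed(2)
  y <- rep(c(0, 1), each = 200)
  good <- y + rnorm(400, sd = 0.7)
  indep <- y + rnorm(400, sd = 0.9)
  X <- cbind(g1 = good, g2 = good, ind = indep)  # g2: exact duplicate
  sel <- cfs_select(X, y, n_select = 2)
  # the second pick must avoid the duplicate of the first
  expect_setequal(sel, c("g1", "ind"))
})

test_that("constant features never outrank informative ones", {
  set.seed(3)
  y <- rep(c(0, 1), each = 30)
  X <- cbind(flat = rep(1, 60), inf1 = y + rnorm(60), inf2 = y + rnorm(60))
  sel <- cfs_select(X, y, n_select = 2)
  expect_false("flat" %in% sel)
})

test_that("the subject-independence screen drops sign-inconsistent features", {
  set.seed(4)
  subj <- rep(1:10, each = 20)
  y <- rep(rep(c(0, 1), 5), each = 20)  # condition constant within subject
  consistent <- y + rnorm(200, sd = 0.6)
  # flips association for half the subjects: pooled r is noisy, signs disagree
  flip <- rep(rep(c(1, -1), each = 20), 5)
  inconsistent <- flip * (y - 0.5) * 3 + rnorm(200, sd = 0.1)
  X <- cbind(cons = consistent, incons = inconsistent, n1 = rnorm(200),
             n2 = rnorm(200))
  sel <- cfs_select(X, y, n_select = 1, subjects = subj)
  expect_equal(sel[1], "cons")
})

test_that("two points embed at their Euclidean distance", {
  X <- rbind(c(0, 0), c(3, 4))
  tr <- isomap_embed(X, k_neighbors = 1)
  expect_equal(abs(diff(tr$values)), 5, tolerance = 1e-9)
  expect_equal(mean(tr$values), 0, tolerance = 1e-12)
})

test_that("noiseless collinear points are ordered perfectly by the embedding", {
  set.seed(5)
  pos <- sort(runif(50))
  dirv <- rnorm(5)
  X <- outer(pos, dirv / sqrt(sum(dirv^2)))
  tr <- isomap_embed(X, k_neighbors = 5)
  expect_equal(abs(cor(tr$values, pos, method = "spearman")), 1)
})

test_that("a quarter-circle arc unrolls to arc length, not chord length", {
  th <- seq(0, pi / 2, length.out = 100)
  X <- cbind(cos(th), sin(th))
  tr <- isomap_embed(X, k_neighbors = 5)
  d_emb <- as.vector(dist(tr$values))
  d_arc <- as.vector(dist(th))  # arc length on the unit circle
  expect_gt(cor(d_emb, d_arc), 0.99)
  d_chord <- as.vector(dist(X))
  expect_gt(cor(d_emb, d_arc), cor(d_emb, d_chord))
})

test_that("the embedding is invariant to rigid motions up to sign", {
  set.seed(6)
  X <- matrix(rnorm(30 * 3), 30)
  th <- 0.7
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  X2 <- sweep(X %*% R, 2, c(5, -3, 2), "+")
  t1 <- isomap_embed(X, k_neighbors = 6)$values
  t2 <- isomap_embed(X2, k_neighbors = 6)$values
  expect_equal(abs(t1), abs(t2), tolerance = 1e-8)
})

test_that("with a full neighbourhood on a line the embedding matches classical MDS", {
  set.seed(7)
  pos <- sort(rnorm(20))
  X <- cbind(pos, 2 * pos, -pos)
  tr <- isomap_embed(X, k_neighbors = 19)
  mds <- stats::cmdscale(dist(X), k = 1)[, 1]  # independent oracle
  mds <- mds - mean(mds)
  if (sign(mds[which(abs(mds) > 1e-12)[1]]) != sign(tr$values[which(abs(tr$values) > 1e-12)[1]]))
    mds <- -mds
  expect_equal(tr$values, mds, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a disconnected neighbourhood graph grows k until connected", {
  X <- rbind(matrix(rnorm(10, sd = 0.01), 5), matrix(rnorm(10, sd = 0.01) + 50, 5))
  expect_message(tr <- isomap_embed(X, k_neighbors = 1), "increasing k")
  expect_length(tr$values, 10)
  expect_equal(mean(tr$values), 0, tolerance = 1e-12)
})

test_that("the trajectory output is zero-mean with a positive leading sign", {
  set.seed(8)
  X <- matrix(rnorm(40 * 4), 40)
  tr <- isomap_embed(X, k_neighbors = 8)
  expect_lt(abs(mean(tr$values)), 1e-9 * sd(tr$values))
  nz <- which(abs(tr$values) > 1e-12)
  expect_gt(tr$values[nz[1]], 0)
})
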