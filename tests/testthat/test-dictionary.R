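test_that("patch extraction matches a naive slicing oracle", {
  img <- matrix(runif(16), 4, 4)
  pe <- extract_patches(img, 3)
  expect_equal(nrow(pe$patches), 4)          # (4-3+1)^2
  set.seed(31)
  img <- matrix(runif(64), 8, 8)
  pe <- extract_patches(img, 3)
  i <- 0
  for (r in 1:6) for (c in 1:6) {
    # origins are row-major ordered
    i <- which(pe$origins[, 1] == r & pe$origins[, 2] == c)
    expect_length(i, 1)
    expect_equal(pe$patches[i, ], as.vector(img[r:(r + 2), c:(c + 2)]),
                 tolerance = 1e-15)
  }
  # constant image: identical patch vectors
  pc <- extract_patches(matrix(0.3, 5, 5), 3)
  expect_true(all(pc$patches == 0.3))
  expect_error(extract_patches(img, 4), "odd")
  expect_error(extract_patches(img, 9), "exceeds")
})

test_that("k-means dictionary recovers two constant patch values", {
  patches <- rbind(matrix(0.1, 10, 9), matrix(0.9, 10, 9))
  d <- build_dictionary(patches, 2, seed = 1)
  expect_equal(sort(d$centers[, 1]), c(0.1, 0.9), tolerance = 1e-9)
  expect_true(all(d$centers == d$centers[, 1]))     # constant atoms
  expect_equal(length(unique(d$assignments[1:10])), 1)
  expect_false(d$assignments[1] == d$assignments[11])
  # k = 1: center is the mean patch
  d1 <- build_dictionary(patches, 1, seed = 1)
  expect_equal(d1$centers[1, ], colMeans(patches), tolerance = 1e-12)
  # determinism
  set.seed(77); p2 <- matrix(runif(50 * 9), 50, 9)
  da <- build_dictionary(p2, 5, seed = 4)
  db <- build_dictionary(p2, 5, seed = 4)
  expect_identical(da$assignments, db$assignments)
  expect_error(build_dictionary(p2, 0), "n_atoms")
})

test_that("biadjacency coverage matches enumeration on the 4x4/T=3 case", {
  img <- matrix(runif(16), 4, 4)
  pe <- extract_patches(img, 3)
  d <- build_dictionary(pe$patches, 1, seed = 1)
  G <- build_biadjacency(d, pe$origins, c(4, 4))
  expect_equal(dim(G), c(16, 9))
  rs <- Matrix::rowSums(G)
  cover <- matrix(rs, 4, 4)
  expect_equal(cover[1, 1], 1)    # corner covered by one patch
  expect_equal(cover[2, 2], 4)    # center covered by all four patches
  expect_equal(sum(G), 4 * 9)     # total incidences conserved
})

test_that("biadjacency row sums equal brute-force coverage counts", {
  set.seed(12)
  img <- matrix(runif(144), 12, 12)
  T_ <- 5
  pe <- extract_patches(img, T_)
  d <- build_dictionary(pe$patches, 4, seed = 2)
  G <- build_biadjacency(d, pe$origins, dim(img))
  cover <- matrix(0, 12, 12)
  for (p in seq_len(nrow(pe$origins))) {
    r <- pe$origins[p, 1]; c <- pe$origins[p, 2]
    cover[r:(r + T_ - 1), c:(c + T_ - 1)] <- cover[r:(r + T_ - 1), c:(c + T_ - 1)] + 1
  }
  expect_equal(matrix(Matrix::rowSums(G), 12, 12), cover)
  expect_equal(sum(G), nrow(pe$origins) * T_^2)
  expect_error(build_biadjacency(d, pe$origins, c(5, 5)), "out of range")
})

test_that("label push-forward equals a direct counting oracle", {
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  pe <- extract_patches(img, 3)
  d <- build_dictionary(pe$patches, 1, seed = 3)
  G <- build_biadjacency(d, pe$origins, dim(img))
  lab <- (matrix(runif(64), 8, 8) > 0.5) * 1
  dl <- labels_to_dict(G, list(lab, 1 - lab))
  Gd <- as.matrix(G)
  for (j in 1:9) {
    hits <- sum(Gd[, j] * as.vector(lab))
    covered <- sum(Gd[, j])
    expect_equal(dl$g[j, 1], hits / covered, tolerance = 1e-12)
  }
  # full / empty labels
  dl1 <- labels_to_dict(G, list(matrix(1, 8, 8), matrix(0, 8, 8)))
  expect_true(all(dl1$g[, 1] == 1))
  expect_true(all(dl1$g[, 2] == 0))
})

test_that("area normalization removes the region-size bias", {
  # g_in = g_out = 0.5 with areas 10 vs 30: (0.5/10)/((0.5/10)+(0.5/30)) = 0.75
  dl <- structure(list(g = matrix(0.5, 6, 2), coverage = rep(1, 6),
                       areas = c(10, 30)), class = "dict_labels")
  out <- area_normalize(dl)
  expect_equal(out$g_tilde[, 1], rep(0.75, 6), tolerance = 1e-12)
  # equal areas keep symmetry
  dl$areas <- c(20, 20)
  expect_equal(area_normalize(dl)$g_tilde[, 1], rep(0.5, 6))
  # normalization by construction
  set.seed(2)
  dl$g <- matrix(runif(12), 6, 2); dl$areas <- c(3, 17)
  expect_equal(rowSums(area_normalize(dl)$g_tilde), rep(1, 6), tolerance = 1e-9)
  dl$areas <- c(0, 0)
  expect_error(area_normalize(dl), "areas")
})

test_that("probability pull-back equals the averaging oracle", {
  set.seed(14)
  img <- matrix(runif(64), 8, 8)
  pe <- extract_patches(img, 3)
  d <- build_dictionary(pe$patches, 2, seed = 5)
  G <- build_biadjacency(d, pe$origins, dim(img))
  lab <- (img > median(img)) * 1
  dl <- area_normalize(labels_to_dict(G, list(lab, 1 - lab)))
  pr <- dict_to_probabilities(G, dl, dim(img))
  Gd <- as.matrix(G)
  for (p in sample(1:64, 10)) {
    cov <- which(Gd[p, ] == 1)
    expect_equal(as.vector(pr$E[[1]])[p], mean(dl$g_tilde[cov, 1]),
                 tolerance = 1e-12)
  }
  expect_equal(pr$E[[1]] + pr$E[[2]], matrix(1, 8, 8), tolerance = 1e-9)
  # constant dictionary labels propagate unchanged
  dl$g_tilde <- cbind(rep(1, nrow(dl$g)), rep(0, nrow(dl$g)))
  expect_true(all(dict_to_probabilities(G, dl, dim(img))$E[[1]] == 1))
})

test_that("the multi-label transform sharpens toward the argmax", {
  E <- list(matrix(0.7, 2, 2), matrix(0.3, 2, 2))
  pr <- multi_label_transform(structure(list(E = E, shape = c(2, 2)),
                                        class = "probability_map"))
  expect_equal(pr$E_tilde[[1]], matrix(0.7, 2, 2))   # X = 2: e1/(e1+e2)
  # all-equal layers give 1/2
  E3 <- list(matrix(0.2, 2, 2), matrix(0.2, 2, 2), matrix(0.2, 2, 2))
  pr3 <- multi_label_transform(structure(list(E = E3, shape = c(2, 2)),
                                         class = "probability_map"))
  for (x in 1:3) expect_equal(pr3$E_tilde[[x]], matrix(0.5, 2, 2))
  # E_tilde > 1/2 exactly at the strict argmax
  set.seed(6)
  E3 <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  pr3 <- multi_label_transform(structure(list(E = E3, shape = c(4, 4)),
                                         class = "probability_map"))
  arr <- simplify2array(E3)
  amax <- apply(arr, c(1, 2), which.max)
  for (x in 1:3) {
    expect_equal(pr3$E_tilde[[x]] > 0.5, amax == x)
  }
})

test_that("conservation holds across seeded label configurations", {
  set.seed(55)
  for (rep in 1:5) {
    img <- matrix(runif(14 * 14), 14, 14)
    pe <- extract_patches(img, 3)
    d <- build_dictionary(pe$patches, 6, seed = rep)
    G <- build_biadjacency(d, pe$origins, dim(img))
    for (X in 2:3) {
      lab <- matrix(sample(seq_len(X), 196, replace = TRUE), 14, 14)
      layers <- lapply(seq_len(X), function(x) (lab == x) * 1)
      dl <- area_normalize(labels_to_dict(G, layers))
      expect_equal(rowSums(dl$g_tilde), rep(1, nrow(dl$g_tilde)),
                   tolerance = 1e-9)
      pr <- dict_to_probabilities(G, dl, dim(img))
      expect_equal(Reduce(`+`, pr$E), matrix(1, 14, 14), tolerance = 1e-9)
      expect_equal(sum(G), nrow(pe$origins) * 9)
    }
  }
})
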