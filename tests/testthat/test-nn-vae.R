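test_that("encoder initialization contract: mu near 0, sigma within x2 of 1", {
  set.seed(21)
  enc <- new_encoder(16, n_latent = 10, seed = 3)
  code <- encode(matrix(rnorm(3 * 256), 3), enc)
  expect_equal(ncol(code$mu), 10)         # ten-dimensional latent space
  expect_true(all(abs(code$mu) < 1e-9))   # zero-initialized output head
  expect_true(all(code$sigma >= 0.5 & code$sigma <= 2))
})

test_that("encoding is deterministic for identical images", {
  set.seed(22)
  enc <- new_encoder(16, n_latent = 4, seed = 5)
  # perturb weights so outputs are nontrivial
  enc$net$W[[3]] <- matrix(rnorm(length(enc$net$W[[3]]), 0, 0.05),
                           nrow(enc$net$W[[3]]))
  img <- matrix(rnorm(256), 16, 16)
  c1 <- encode(img, enc)
  c2 <- encode(img, enc)
  expect_identical(c1$mu, c2$mu)
  expect_identical(c1$sigma, c2$sigma)
})

test_that("latent sampling follows the reparameterization", {
  code <- list(mu = c(1, -2, 3), sigma = c(0, 0, 0))
  expect_equal(as.vector(sample_latent(code, 1)), c(1, -2, 3),
               ignore_attr = TRUE)
  code2 <- list(mu = c(0.5, -0.5), sigma = c(1, 2))
  z1 <- sample_latent(code2, 42)
  z2 <- sample_latent(code2, 42)
  expect_equal(unclass(z1), unclass(z2), ignore_attr = TRUE)
  # CLT bound on the sample mean over many draws
  n <- 1e4
  draws <- vapply(seq_len(n), function(i)
    as.vector(sample_latent(code2, i)), numeric(2))
  for (d in 1:2) {
    se <- code2$sigma[d] / sqrt(n)
    expect_lt(abs(mean(draws[d, ]) - code2$mu[d]), 4 * se)
  }
})

test_that("positional encoding has the stated structure", {
  x0 <- positional_encode(c(0, 0, 0))
  expect_equal(length(x0), 63)
  # all sines zero, all cosines one at the origin
  sines <- x0[as.vector(outer(1:3, (0:9) * 6, "+"))]
  cosines <- x0[as.vector(outer(4:6, (0:9) * 6, "+"))]
  expect_true(all(sines == 0))
  expect_true(all(cosines == 1))
  expect_equal(x0[61:63], c(0, 0, 0))
  # injective on a 10^3 lattice
  ax <- seq(-0.9, 0.9, length.out = 10)
  lat <- as.matrix(expand.grid(ax, ax, ax))
  enc <- positional_encode(lat)
  expect_equal(nrow(unique(round(enc, 9))), 1000)
})

test_that("positional encoding backward matches finite differences", {
  set.seed(23)
  x <- matrix(runif(9, -0.8, 0.8), 3)
  dF <- matrix(rnorm(3 * 63), 3)
  g <- gaussflex:::positional_encode_backward(x, dF)
  h <- 1e-6
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    fd <- (sum(positional_encode(xp) * dF) -
           sum(positional_encode(xm) * dF)) / (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-5)
  }
})

test_that("the decoder is the identity at initialization and deterministic", {
  dec <- new_decoder(n_latent = 4, coord_scale = 60, hidden = 24, seed = 7)
  pos <- matrix(runif(15, -40, 40), 5)
  z <- rnorm(4)
  D <- decode_deformation(dec, z, pos)
  expect_equal(D, pos)
  # determinism after perturbing weights
  dec$net$W[[8]] <- matrix(rnorm(24 * 3, 0, 0.1), 24, 3)
  D1 <- decode_deformation(dec, z, pos)
  D2 <- decode_deformation(dec, z, pos)
  expect_identical(D1, D2)
  expect_false(isTRUE(all.equal(D1, pos)))
})

test_that("decoder position-Jacobian matches finite differences", {
  set.seed(24)
  dec <- new_decoder(n_latent = 3, coord_scale = 36, hidden = 16, seed = 9)
  dec$net$W[[8]] <- matrix(rnorm(16 * 3, 0, 0.1), 16, 3)
  z <- rnorm(3)
  pos <- matrix(runif(9, -20, 20), 3)
  dD <- matrix(rnorm(9), 3)
  fw <- gaussflex:::dec_forward(dec, matrix(z, 1), pos)
  bk <- gaussflex:::dec_backward(dec, fw, dD)
  h <- 1e-4
  for (k in seq_along(pos)) {
    pp <- pos; pp[k] <- pp[k] + h
    pm <- pos; pm[k] <- pm[k] - h
    fd <- (sum(decode_deformation(dec, z, pp) * dD) -
           sum(decode_deformation(dec, z, pm) * dD)) / (2 * h)
    expect_equal(bk$dC[k], fd, tolerance = 1e-3)
  }
})

test_that("MLP parameter gradients match finite differences", {
  set.seed(25)
  net <- gaussflex:::mlp_new(c(4, 8, 8, 2), activation = "elu",
                             final_zero = FALSE, seed = 11)
  X <- matrix(rnorm(12), 3)
  dOut <- matrix(rnorm(6), 3)
  fw <- gaussflex:::mlp_forward(net, X)
  bk <- gaussflex:::mlp_backward(net, fw, dOut)
  grads <- gaussflex:::mlp_grad_list(bk)
  pars <- gaussflex:::mlp_params(net)
  h <- 1e-5
  for (l in seq_along(pars)) {
    k <- 1
    p2 <- pars; p2[[l]][k] <- p2[[l]][k] + h
    f1 <- sum(gaussflex:::mlp_forward(
      gaussflex:::mlp_set_params(net, p2), X)$out * dOut)
    p2[[l]][k] <- p2[[l]][k] - 2 * h
    f2 <- sum(gaussflex:::mlp_forward(
      gaussflex:::mlp_set_params(net, p2), X)$out * dOut)
    expect_equal(grads[[l]][k], (f1 - f2) / (2 * h), tolerance = 1e-4)
  }
})
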