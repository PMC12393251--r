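# Ideal helix construction, twist selection and circular bending.

test_that("linear helix sites satisfy the helical trajectory equations", {
  par <- default_helix_parameters()
  N <- 30
  conf <- build_linear_helix(par, N, fix_seq(N))
  tab <- par$table
  for (k in seq_len(nrow(tab))) {
    a <- conf$sites[conf$sites$strand == tab$strand[k] &
                      conf$sites$atom == tab$atom[k], ]
    a <- a[order(a$nt), ]
    ang <- (a$nt * par$twist + tab$theta0[k]) * pi / 180
    expect_equal(a$x, tab$r[k] * cos(ang), tolerance = 1e-12)
    expect_equal(a$y, tab$r[k] * sin(ang), tolerance = 1e-12)
    # constant rise between successive nucleotides
    expect_equal(diff(a$z), rep(par$rise, N - 1), tolerance = 1e-12)
    expect_equal(a$z[1], tab$z0[k], tolerance = 1e-12)
  }
  # a site with r = 9, theta0 = 0, z0 = 0 sits at (9, 0, 0) for n = 0
  tab2 <- tab; tab2$r[1] <- 9; tab2$theta0[1] <- 0; tab2$z0[1] <- 0
  c2 <- build_linear_helix(helix_parameters(tab2, par$twist, par$rise), 2, "AC")
  s0 <- c2$sites[c2$sites$strand == 1 & c2$sites$atom == "S" & c2$sites$nt == 0, ]
  expect_equal(unlist(s0[, c("x", "y", "z")]), c(x = 9, y = 0, z = 0))
})

test_that("two full turns over 21 steps at the B-DNA twist", {
  par <- default_helix_parameters()        # twist 360/10.5
  conf <- build_linear_helix(par, 30, fix_seq(30))
  s <- conf$sites
  for (n in 0:8) {
    a <- s[s$strand == 1 & s$atom == "P" & s$nt == n, ]
    b <- s[s$strand == 1 & s$atom == "P" & s$nt == n + 21, ]
    expect_equal(c(a$x, a$y), c(b$x, b$y), tolerance = 1e-6)
  }
})

test_that("builder validates its inputs", {
  par <- default_helix_parameters()
  expect_error(build_linear_helix(par, 0, ""), "positive integer")
  expect_error(build_linear_helix(par, 4, "ACGU"), "invalid sequence")
  expect_error(build_linear_helix(par, 4, "ACG"), "does not match")
})

test_that("circle twist is the nearest integer number of turns", {
  ct <- choose_circle_twist(105)
  expect_identical(ct$Lk, 10L)
  expect_equal(ct$twist, 3600 / 105)
  ct90 <- choose_circle_twist(90)          # round(90/10.5) = round(8.571) = 9
  expect_identical(ct90$Lk, 9L)
  expect_equal(ct90$twist, 36)
  for (N in c(63, 85, 90, 105, 150)) {
    tw <- choose_circle_twist(N)$twist
    expect_equal((N * tw) %% 360, 0)
  }
  expect_error(choose_circle_twist(2), ">= 3")
})

test_that("circular bending fixes the centreline and preserves radii", {
  R <- 50
  # centre of mass at origin, so the translation moves sites to y = R
  conf <- bare_conformation(rbind(c(0, 0, 0),
                                  c(0, 0, pi * R / 2), c(0, 0, -pi * R / 2),
                                  c(0, 0, 2 * pi * R), c(0, 0, -2 * pi * R)))
  bent <- circularize(conf, R)
  got <- as.matrix(bent$sites[, c("x", "y", "z")])
  expect_equal(got[1, ], c(x = 0, y = R, z = 0), tolerance = 1e-9)
  expect_equal(got[2, ], c(x = 0, y = 0, z = R), tolerance = 1e-9)
  expect_equal(got[3, ], c(x = 0, y = 0, z = -R), tolerance = 1e-9)
  # the arc closes after one full circumference
  expect_equal(got[4, ], c(x = 0, y = R, z = 0), tolerance = 1e-9)
  expect_equal(got[5, ], c(x = 0, y = R, z = 0), tolerance = 1e-9)
})

test_that("bending preserves x and the distance from the bending axis", {
  par0 <- default_helix_parameters()
  ct <- choose_circle_twist(105)
  par <- helix_parameters(par0$table, ct$twist, par0$rise)
  lin <- build_linear_helix(par, 105, fix_seq(105))
  R <- 105 * par$rise / (2 * pi)
  # radial coordinate before bending, after the translation to (0, R, 0)
  y_before <- lin$sites$y - mean(lin$sites$y) + R
  circ <- circularize(lin)
  expect_equal(circ$sites$x, lin$sites$x - mean(lin$sites$x), tolerance = 1e-12)
  expect_equal(sqrt(circ$sites$y^2 + circ$sites$z^2), y_before,
               tolerance = 1e-12)
  expect_error(circularize(circ), "already circular")
  expect_error(circularize(lin, R = 5), "singular transform")
})

test_that("the closed helix is continuous across the ligation seam", {
  mc <- build_minicircle(105, fix_seq(105))
  s <- mc$conformation$sites
  g <- function(st, n, a)
    unlist(s[s$strand == st & s$nt == n & s$atom == a, c("x", "y", "z")])
  seam <- sqrt(sum((g(1, 104, "S") - g(1, 0, "P"))^2))
  typical <- sqrt(sum((g(1, 50, "S") - g(1, 51, "P"))^2))
  expect_lt(abs(seam - typical) / typical, 0.10)
  # strand 2 seam runs the other way
  seam2 <- sqrt(sum((g(2, 0, "S") - g(2, 104, "P"))^2))
  typical2 <- sqrt(sum((g(2, 51, "S") - g(2, 50, "P"))^2))
  expect_lt(abs(seam2 - typical2) / typical2, 0.10)
})

test_that("helix parameters round-trip through a reference duplex", {
  par <- default_helix_parameters()
  lin <- build_linear_helix(par, 90, fix_seq(90))
  rec <- derive_helix_parameters(lin)
  expect_equal(rec$twist, par$twist, tolerance = 1e-6)
  expect_equal(rec$rise, par$rise, tolerance = 1e-6)
  expect_equal(rec$table$r, par$table$r, tolerance = 1e-6)
  expect_equal(rec$table$theta0, par$table$theta0, tolerance = 1e-6)
  expect_equal(rec$table$z0, par$table$z0, tolerance = 1e-6)
})

test_that("parameter derivation averages out a single-site perturbation", {
  par <- default_helix_parameters()
  lin <- build_linear_helix(par, 90, fix_seq(90))
  eps <- 0.1
  i <- which(lin$sites$strand == 1 & lin$sites$atom == "B" &
               lin$sites$nt == 40)
  lin$sites$x[i] <- lin$sites$x[i] + eps
  rec <- derive_helix_parameters(lin)
  dr <- abs(rec$table$r - par$table$r)
  dz <- abs(rec$table$z0 - par$table$z0)
  expect_true(all(dr < eps) && all(dz < eps))
  expect_true(all(abs(rec$table$theta0 - par$table$theta0) <
                    eps / min(par$table$r) * 180 / pi))
  expect_error(derive_helix_parameters(build_linear_helix(par, 2, "AC")),
               "at least 3 bp")
})
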