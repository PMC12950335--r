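test_that("expand_multiplet reproduces first-order patterns", {
  # singlet identity
  s <- expand_multiplet(NULL)
  expect_equal(s$offset, 0)
  expect_equal(s$weight, 1)

  # quartet from three equivalent partners at J = 7 Hz (Pascal weights)
  q <- expand_multiplet(data.frame(J = 7, n_partner = 3))
  expect_equal(q$offset, c(-10.5, -3.5, 3.5, 10.5))
  expect_equal(q$weight, c(1, 3, 3, 1) / 8)

  # doublet-of-doublets: brute-force convolution of two doublets
  dd <- expand_multiplet(data.frame(J = c(10, 4), n_partner = c(1, 1)))
  brute <- sort(as.vector(outer(c(-5, 5), c(-2, 2), `+`)))
  expect_equal(dd$offset, brute)
  expect_equal(dd$weight, rep(1 / 4, 4))

  expect_error(expand_multiplet(data.frame(J = -1, n_partner = 1)), "J")
})

test_that("multiplet weights sum to one and offsets are symmetric", {
  set.seed(42)
  for (rep in 1:20) {
    n_c <- sample(1:3, 1)
    cp <- data.frame(J = runif(n_c, 0.5, 15), n_partner = sample(1:4, n_c,
                                                                 TRUE))
    m <- expand_multiplet(cp)
    expect_equal(sum(m$weight), 1, tolerance = 1e-12)
    expect_equal(m$offset, -rev(m$offset), tolerance = 1e-9)
  }
})

test_that("peaklist expands systems into diagonal and cross blocks", {
  # one uncoupled singlet: exactly one diagonal peak, no cross peaks
  mix1 <- mixture_spec(list(spin_system("x", data.frame(
    label = "a", shift = 2, n_protons = 1))), faraway_water_fraction = 0)
  pk1 <- peaklist(mix1)
  expect_equal(nrow(pk1), 1L)
  expect_equal(pk1$kind, "diagonal")
  expect_equal(pk1$amplitude, 1)

  # ethanol: triplet/quartet diagonals plus mirror-symmetric cross blocks
  eth <- mixture_spec(list(spin_system("ethanol", data.frame(
    label = c("CH3", "CH2"), shift = c(1.18, 3.65), n_protons = c(3, 2)),
    data.frame(site_a = "CH3", site_b = "CH2", J = 7),
    concentration = 2, klass = "solvent")), faraway_water_fraction = 0)
  pk <- peaklist(eth)
  di <- pk[pk$kind == "diagonal", ]
  cr <- pk[pk$kind == "cross", ]
  # CH3 is a triplet (3 lines), CH2 a quartet (4 lines)
  expect_equal(nrow(di), 3^2 + 4^2)
  expect_equal(nrow(cr), 2 * 3 * 4)
  expect_equal(sum(di$amplitude[di$f1_center == 1.18]), 2 * 3)
  # enumeration: every cross entry has its mirror with equal amplitude
  key <- function(a, b) paste(round(a, 6), round(b, 6))
  m <- match(key(cr$f1, cr$f2), key(cr$f2, cr$f1))
  expect_false(anyNA(m))
  expect_equal(cr$amplitude, cr$amplitude[m])
})

test_that("empty mixture gives an empty peak list", {
  pk <- peaklist(mixture_spec(list(), faraway_water_fraction = 0))
  expect_equal(nrow(pk), 0L)
})

test_that("wine fixture peak count matches an enumeration oracle", {
  mix <- wine_fixture()
  pk <- peaklist(mix)
  # oracle: lines per site = product over its couplings of (n_partner + 1);
  # diagonal contributes lines^2 per site, each coupling 2 * lines_a * lines_b,
  # plus one faraway-water copy of the water diagonal block
  expected <- 0L
  for (sys in mix$systems) {
    lines <- vapply(sys$sites$label, function(lb) {
      hit <- sys$couplings$site_a == lb | sys$couplings$site_b == lb
      partner <- ifelse(sys$couplings$site_a[hit] == lb,
                        sys$couplings$site_b[hit], sys$couplings$site_a[hit])
      prod(sys$sites$n_protons[match(partner, sys$sites$label)] + 1)
    }, 0)
    expected <- expected + sum(lines^2) +
      sum(2 * lines[sys$couplings$site_a] * lines[sys$couplings$site_b])
  }
  expected <- expected + 1L  # faraway water (water is an uncoupled singlet)
  expect_equal(nrow(pk), as.integer(expected))
})

test_that("wine fixture carries the calibration anchors and solvent excess", {
  mix <- wine_fixture()
  shifts <- unlist(lapply(mix$systems, function(s) s$sites$shift))
  expect_true(0.00 %in% shifts)   # TSP reference
  expect_true(4.47 %in% shifts)   # tartrate
  expect_true(length(mix$systems) >= 15 && length(mix$systems) <= 25)
  cls <- vapply(mix$systems, `[[`, "", "klass")
  conc <- vapply(mix$systems, `[[`, 0, "concentration")
  expect_gte(max(conc[cls == "solvent"]) / max(conc[cls == "metabolite"]),
             1e3)
  non_water <- unlist(lapply(mix$systems[names(mix$systems) != "water"],
                             function(s) s$sites$shift))
  expect_true(all(non_water >= 0 & non_water <= 6))
})

test_that("peak amplitudes are linear in concentration", {
  base <- tiny_mix()
  scaled <- base
  scaled$systems$lactate$concentration <-
    scaled$systems$lactate$concentration * 3.5
  pk0 <- peaklist(base)
  pk1 <- peaklist(scaled)
  lac <- pk0$system == "lactate"
  expect_equal(pk1$amplitude[lac], 3.5 * pk0$amplitude[lac])
  expect_equal(pk1$amplitude[!lac], pk0$amplitude[!lac])
})

test_that("cross-peak mirror symmetry holds for generated mixtures", {
  set.seed(11)
  for (rep in 1:5) {
    sys <- spin_system("s", data.frame(
      label = c("a", "b", "c"), shift = sort(runif(3, 0.5, 5)),
      n_protons = sample(1:3, 3, TRUE)),
      data.frame(site_a = c("a", "b"), site_b = c("b", "c"),
                 J = runif(2, 2, 12)),
      concentration = runif(1, 0.5, 50))
    pk <- peaklist(mixture_spec(list(sys), faraway_water_fraction = 0))
    cr <- pk[pk$kind == "cross", ]
    key <- function(a, b) paste(round(a, 6), round(b, 6))
    m <- match(key(cr$f1, cr$f2), key(cr$f2, cr$f1))
    expect_false(anyNA(m))
    expect_equal(cr$amplitude, cr$amplitude[m])
  }
})

test_that("mixture tables round-trip through TSV", {
  mix <- tiny_mix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mixture(mix, path)
  back <- read_mixture(path)
  expect_equal(names(back$systems), names(mix$systems))
  for (nm in names(mix$systems)) {
    expect_equal(back$systems[[nm]]$sites, mix$systems[[nm]]$sites,
                 ignore_attr = TRUE)
    expect_equal(back$systems[[nm]]$concentration,
                 mix$systems[[nm]]$concentration)
    expect_equal(nrow(back$systems[[nm]]$couplings),
                 nrow(mix$systems[[nm]]$couplings))
  }
  expect_equal(peaklist(back), peaklist(mix), ignore_attr = TRUE)
})

test_that("invalid spin systems are rejected", {
  expect_error(spin_system("x", data.frame(label = "a", shift = Inf,
                                           n_protons = 1)), "finite")
  expect_error(spin_system("x", data.frame(label = "a", shift = 1,
                                           n_protons = 0)), "n_protons")
  expect_error(spin_system("x", data.frame(label = "a", shift = 1,
                                           n_protons = 1),
                           data.frame(site_a = "a", site_b = "a", J = 7)),
               "couple to itself")
  expect_error(mixture_spec(list(), faraway_water_fraction = 0.5),
               "faraway")
})
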