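#' Spin systems and mixtures
#'
#' A `spin_system` is a named set of proton sites (chemical shift in ppm,
#' number of equivalent protons) connected by scalar couplings (J in Hz),
#' with a relative concentration, a class (`"metabolite"`, `"solvent"` or
#' `"reference"`) and a transverse relaxation time T2.  The representation is
#' first-order (weak coupling): every site produces a binomial multiplet and
#' every coupling a pair of COSY cross-peak blocks.  Strong coupling,
#' chemical exchange and antiphase cross-peak fine structure are out of
#' scope.
#'
#' @param name System name (e.g. `"ethanol"`).
#' @param sites `data.frame` with columns `label`, `shift` (ppm),
#'   `n_protons` (>= 1).
#' @param couplings `data.frame` with columns `site_a`, `site_b` (labels
#'   present in `sites`) and `J` (Hz, > 0), or `NULL` for an uncoupled
#'   system.
#' @param concentration Relative amplitude (arbitrary units, >= 0).
#' @param klass One of `"metabolite"`, `"solvent"`, `"reference"`.
#' @param T2 Transverse relaxation time in seconds (> 0).
#' @return An object of class `uf_spin_system`.
#' @export
spin_system <- function(name, sites, couplings = NULL, concentration = 1,
                        klass = c("metabolite", "solvent", "reference"),
                        T2 = 0.3) {
  klass <- match.arg(klass)
  stopifnot(is.data.frame(sites),
            all(c("label", "shift", "n_protons") %in% names(sites)))
  if (any(!is.finite(sites$shift))) stop("site shifts must be finite")
  if (any(sites$n_protons < 1)) stop("n_protons must be >= 1")
  if (anyDuplicated(sites$label)) stop("site labels must be unique")
  stopifnot_scalar_num(concentration, "concentration", nonneg = TRUE)
  stopifnot_scalar_num(T2, "T2", positive = TRUE)
  if (!is.null(couplings) && nrow(couplings)) {
    stopifnot(all(c("site_a", "site_b", "J") %in% names(couplings)))
    if (any(couplings$J <= 0)) stop("coupling constants J must be > 0")
    if (any(couplings$site_a == couplings$site_b))
      stop("a site cannot couple to itself")
    known <- c(couplings$site_a, couplings$site_b) %in% sites$label
    if (!all(known)) stop("coupling references an unknown site label")
  } else {
    couplings <- data.frame(site_a = character(), site_b = character(),
                            J = numeric())
  }
  structure(list(name = name, sites = sites, couplings = couplings,
                 concentration = concentration, klass = klass, T2 = T2),
            class = "uf_spin_system")
}

#' Mixture specification
#'
#' Bundles spin systems with two mixture-level parameters: the fraction of
#' the water signal arising from "faraway" nuclei at the edge of the
#' radiofrequency coil (which see an off-nominal flip angle, escape the
#' frequency-selective suppression pulse and are only removed by the NOESY
#' block), and the phenomenological COSY coherence-transfer efficiency
#' `cross_transfer` scaling cross-peak amplitudes relative to diagonal
#' amplitudes.
#'
#' @param systems List of [spin_system()] objects.
#' @param faraway_water_fraction Fraction of the water amplitude assigned to
#'   the faraway-water sub-population, in `[0, 0.1]`.
#' @param cross_transfer Cross-peak amplitude scale in `(0, 1]`.
#' @return An object of class `uf_mixture`.
#' @export
mixture_spec <- function(systems, faraway_water_fraction = 1e-3,
                         cross_transfer = 0.3) {
  stopifnot(is.list(systems),
            all(vapply(systems, inherits, TRUE, "uf_spin_system")))
  stopifnot_scalar_num(faraway_water_fraction, "faraway_water_fraction",
                       nonneg = TRUE)
  if (faraway_water_fraction > 0.1)
    stop("faraway_water_fraction must be in [0, 0.1]")
  stopifnot_scalar_num(cross_transfer, "cross_transfer", positive = TRUE)
  if (cross_transfer > 1) stop("cross_transfer must be in (0, 1]")
  names(systems) <- vapply(systems, `[[`, "", "name")
  if (anyDuplicated(names(systems))) stop("system names must be unique")
  structure(list(systems = systems,
                 faraway_water_fraction = faraway_water_fraction,
                 cross_transfer = cross_transfer), class = "uf_mixture")
}

#' @export
print.uf_mixture <- function(x, ...) {
  cls <- vapply(x$systems, `[[`, "", "klass")
  cat(sprintf("Mixture of %d spin systems (%d solvent, %d reference, %d metabolite)\n",
              length(x$systems), sum(cls == "solvent"),
              sum(cls == "reference"), sum(cls == "metabolite")))
  cat(sprintf("  faraway water fraction %.3g, cross transfer %.2f\n",
              x$faraway_water_fraction, x$cross_transfer))
  invisible(x)
}

#' First-order multiplet expansion
#'
#' Expands the resonance of a site coupled to one or more sets of equivalent
#' partner protons into its first-order multiplet: each coupling `(J, n)`
#' contributes `n + 1` lines with Pascal's-triangle (binomial) weights, and
#' multiple couplings combine by convolution (e.g. a doublet-of-doublets).
#' Offsets are symmetric about zero and weights sum to one.
#'
#' @param couplings `data.frame` (or list coercible to one) with columns `J`
#'   (Hz, > 0) and `n_partner` (equivalent partner protons, >= 1).  Zero rows
#'   give the singlet.
#' @param tol Offsets closer than `tol` Hz are merged and their weights
#'   summed.
#' @return `data.frame` with columns `offset` (Hz, sorted) and `weight`.
#' @export
#' @examples
#' expand_multiplet(data.frame(J = 7, n_partner = 3)) # 1:3:3:1 quartet
expand_multiplet <- function(couplings = NULL, tol = 1e-9) {
  off <- 0; w <- 1
  if (!is.null(couplings) && NROW(couplings)) {
    couplings <- as.data.frame(couplings)
    if (any(couplings$J < 0)) stop("coupling constants J must be >= 0")
    if (any(couplings$n_partner < 1)) stop("n_partner must be >= 1")
    for (r in seq_len(nrow(couplings))) {
      J <- couplings$J[r]; n <- couplings$n_partner[r]
      k <- 0:n
      line_off <- J * (k - n / 2)
      line_w <- choose(n, k) / 2^n
      off <- as.vector(outer(off, line_off, `+`))
      w <- as.vector(outer(w, line_w, `*`))
    }
    # merge coincident lines (e.g. the centre line of a triplet)
    grp <- round(off / tol)
    w <- tapply(w, grp, sum)
    off <- tapply(off, grp, mean)
  }
  o <- order(off)
  data.frame(offset = as.numeric(off)[o], weight = as.numeric(w)[o],
             row.names = NULL)
}

# 1D multiplet of one site within its system: all couplings touching the
# site, the partner multiplicity being the partner site's proton count.
site_multiplet <- function(sys, label) {
  cp <- sys$couplings
  hit <- cp$site_a == label | cp$site_b == label
  if (!any(hit)) return(expand_multiplet(NULL))
  partner <- ifelse(cp$site_a[hit] == label, cp$site_b[hit], cp$site_a[hit])
  n <- sys$sites$n_protons[match(partner, sys$sites$label)]
  expand_multiplet(data.frame(J = cp$J[hit], n_partner = n))
}

#' Expand a mixture into its 2D peak list
#'
#' Every site contributes a diagonal multiplet block (the outer product of
#' its 1D multiplet with itself) of total amplitude
#' `concentration * n_protons`; every coupling contributes a pair of
#' mirror-symmetric cross-peak blocks of total amplitude
#' `cross_transfer * concentration * sqrt(n_a * n_b)` each, the f1 structure
#' taken from one site's multiplet and the f2 structure from the other's.
#' If the mixture contains a solvent system named `"water"`, an additional
#' faraway-water diagonal block of amplitude
#' `faraway_water_fraction * water amplitude` is appended and flagged so the
#' suppression model can treat it separately.
#'
#' @param mix A [mixture_spec()] object.
#' @param larmor Proton Larmor frequency in MHz, used to convert multiplet
#'   splittings from Hz to ppm.
#' @return `data.frame` with columns `f1`, `f2` (ppm), `amplitude`, `T2`
#'   (s), `kind` (`"diagonal"`/`"cross"`), `system`, `class`, `faraway`.
#'   Empty mixtures give a zero-row frame.
#' @export
peaklist <- function(mix, larmor = 700.28) {
  stopifnot(inherits(mix, "uf_mixture"))
  out <- list()
  for (sys in mix$systems) {
    if (sys$concentration == 0) next
    mults <- lapply(sys$sites$label, site_multiplet, sys = sys)
    names(mults) <- sys$sites$label
    for (si in seq_len(nrow(sys$sites))) {
      m <- mults[[si]]
      amp <- sys$concentration * sys$sites$n_protons[si]
      g <- expand.grid(i = seq_len(nrow(m)), j = seq_len(nrow(m)))
      out[[length(out) + 1L]] <- data.frame(
        f1 = sys$sites$shift[si] + m$offset[g$i] / larmor,
        f2 = sys$sites$shift[si] + m$offset[g$j] / larmor,
        f1_center = sys$sites$shift[si], f2_center = sys$sites$shift[si],
        amplitude = amp * m$weight[g$i] * m$weight[g$j],
        T2 = sys$T2, kind = "diagonal", system = sys$name,
        class = sys$klass, faraway = FALSE)
    }
    if (nrow(sys$couplings)) for (ci in seq_len(nrow(sys$couplings))) {
      a <- sys$couplings$site_a[ci]; b <- sys$couplings$site_b[ci]
      ia <- match(a, sys$sites$label); ib <- match(b, sys$sites$label)
      amp <- mix$cross_transfer * sys$concentration *
        sqrt(sys$sites$n_protons[ia] * sys$sites$n_protons[ib])
      for (pair in list(c(ia, ib), c(ib, ia))) {
        m1 <- mults[[pair[1]]]; m2 <- mults[[pair[2]]]
        g <- expand.grid(i = seq_len(nrow(m1)), j = seq_len(nrow(m2)))
        out[[length(out) + 1L]] <- data.frame(
          f1 = sys$sites$shift[pair[1]] + m1$offset[g$i] / larmor,
          f2 = sys$sites$shift[pair[2]] + m2$offset[g$j] / larmor,
          f1_center = sys$sites$shift[pair[1]],
          f2_center = sys$sites$shift[pair[2]],
          amplitude = amp * m1$weight[g$i] * m2$weight[g$j],
          T2 = sys$T2, kind = "cross", system = sys$name,
          class = sys$klass, faraway = FALSE)
      }
    }
  }
  pk <- if (length(out)) do.call(rbind, out) else
    data.frame(f1 = numeric(), f2 = numeric(), f1_center = numeric(),
               f2_center = numeric(), amplitude = numeric(),
               T2 = numeric(), kind = character(), system = character(),
               class = character(), faraway = logical())
  if (mix$faraway_water_fraction > 0 && "water" %in% names(mix$systems) &&
      mix$systems[["water"]]$klass == "solvent") {
    far <- pk[pk$system == "water" & pk$kind == "diagonal", , drop = FALSE]
    if (nrow(far)) {
      far$amplitude <- far$amplitude * mix$faraway_water_fraction
      far$faraway <- TRUE
      pk <- rbind(pk, far)
    }
  }
  rownames(pk) <- NULL
  pk
}

#' Read / write mixture tables
#'
#' Mixtures are exchanged as TSV with one row per site and columns `system`,
#' `site`, `shift_ppm`, `n_protons`, `J_partner`, `J_hz`, `concentration`,
#' `class`, `T2_s`.  A row whose `(system, site)` pair repeats an earlier row
#' adds a further coupling to that site.  Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @param faraway_water_fraction,cross_transfer Passed to [mixture_spec()].
#' @return [read_mixture()] returns a [mixture_spec()];
#'   [write_mixture()] invisibly returns `path`.
#' @export
read_mixture <- function(path, faraway_water_fraction = 1e-3,
                         cross_transfer = 0.3) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("system", "site", "shift_ppm", "n_protons", "J_partner", "J_hz",
            "concentration", "class", "T2_s")
  if (!all(need %in% names(tb)))
    stop("mixture table must have columns: ", paste(need, collapse = ", "))
  systems <- lapply(split(tb, factor(tb$system, unique(tb$system))), function(d) {
    first <- !duplicated(d$site)
    sites <- data.frame(label = d$site[first], shift = d$shift_ppm[first],
                        n_protons = d$n_protons[first])
    has_j <- !is.na(d$J_hz) & nzchar(trimws(ifelse(is.na(d$J_partner), "",
                                                   d$J_partner)))
    cpl <- if (any(has_j))
      unique(data.frame(site_a = d$site[has_j], site_b = d$J_partner[has_j],
                        J = d$J_hz[has_j]))
    spin_system(d$system[1], sites, cpl, concentration = d$concentration[1],
                klass = d$class[1], T2 = d$T2_s[1])
  })
  mixture_spec(unname(systems), faraway_water_fraction, cross_transfer)
}

#' @rdname read_mixture
#' @param mix A [mixture_spec()] object.
#' @export
write_mixture <- function(mix, path) {
  stopifnot(inherits(mix, "uf_mixture"))
  rows <- lapply(mix$systems, function(sys) {
    d <- data.frame(system = sys$name, site = sys$sites$label,
                    shift_ppm = sys$sites$shift,
                    n_protons = sys$sites$n_protons,
                    J_partner = NA_character_, J_hz = NA_real_,
                    concentration = sys$concentration, class = sys$klass,
                    T2_s = sys$T2)
    if (nrow(sys$couplings)) {
      for (ci in seq_len(nrow(sys$couplings))) {
        a <- sys$couplings$site_a[ci]
        i <- match(a, d$site)
        if (is.na(d$J_hz[i])) {
          d$J_partner[i] <- sys$couplings$site_b[ci]
          d$J_hz[i] <- sys$couplings$J[ci]
        } else {
          extra <- d[i, ]
          extra$J_partner <- sys$couplings$site_b[ci]
          extra$J_hz <- sys$couplings$J[ci]
          d <- rbind(d, extra)
        }
      }
    }
    d
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Wine-like mixture fixture
#'
#' A 17-system stand-in for a white wine: water and ethanol solvents several
#' orders of magnitude above the metabolites, the TSP chemical-shift
#' reference singlet at exactly 0.00 ppm, the tartrate singlet at exactly
#' 4.47 ppm (the two calibration anchors), and coupled metabolite systems
#' for lactate, acetate, succinate, isopentanol, isobutanol, acetoin,
#' 1,3-propanediol, myo-inositol and a few further wine constituents.
#' Metabolite shifts other than the two anchors are illustrative
#' literature-style values (see the fixture TSV header), not measured ones.
#'
#' @inheritParams read_mixture
#' @return A [mixture_spec()].
#' @export
#' @examples
#' wf <- wine_fixture()
#' nrow(peaklist(wf))
wine_fixture <- function(faraway_water_fraction = 1e-3,
                         cross_transfer = 0.3) {
  path <- system.file("extdata", "wine_mixture.tsv", package = "ufcosy",
                      mustWork = TRUE)
  read_mixture(path, faraway_water_fraction, cross_transfer)
}
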