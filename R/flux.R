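# Random mass-balanced flux sampling, tracer/readout design screening and
# flux-ratio estimation from measured fractional labeling.

#' Internal-metabolite stoichiometric matrix over net reactions
#'
#' One column per undirected reaction (a reversible pair collapses to its
#' net flux, forward minus backward); one row per internal (non-boundary)
#' metabolite. All stoichiometric coefficients are the small integers
#' implied by the atom maps.
#'
#' @param net a [MetabolicNetwork]
#' @return list with `S` (matrix), `reactions` (net ids), `reversible`
#'   (logical per net id), `internal` (metabolite names)
#' @export
stoichiometricMatrix <- function(net) {
  bnd <- boundaryMetabolites(buildMAM(net))
  internal <- setdiff(names(net@metabolites),
                      c(bnd$substrates, bnd$products))
  bases <- unique(vapply(net@reactions, `[[`, "", "base"))
  rev <- setNames(logical(length(bases)), bases)
  S <- matrix(0, length(internal), length(bases),
              dimnames = list(internal, bases))
  for (r in net@reactions) {
    if (r$dir == "b") { rev[r$base] <- TRUE; next }  # net = forward - backward
    if (r$dir == "f") rev[r$base] <- TRUE
    for (t in r$reactants)
      if (t$met %in% internal) S[t$met, r$base] <- S[t$met, r$base] - 1
    for (t in r$products)
      if (t$met %in% internal) S[t$met, r$base] <- S[t$met, r$base] + 1
  }
  list(S = S, reactions = bases, reversible = rev, internal = internal)
}

.defaultUptake <- function(net) {
  substrates <- boundaryMetabolites(buildMAM(net))$substrates
  for (r in net@reactions)
    if (any(vapply(r$reactants, function(t) t$met %in% substrates, TRUE)))
      return(r$base)
  stop("no reaction consumes a substrate; cannot identify uptake",
       call. = FALSE)
}

#' Sample random mass-balanced flux vectors
#'
#' Draws `n` non-negative steady-state flux vectors with the uptake
#' reaction normalized to 1. Free net fluxes (the non-pivot columns of the
#' internal stoichiometric matrix under column-pivoted QR) are drawn
#' uniformly on \[0, 1\]; dependent fluxes are solved from the mass
#' balances; candidates with a negative irreversible net flux are
#' rejected and redrawn. Each reversible pair additionally receives an
#' exchange flux e drawn log-uniformly on \[1e-3, 10\] (in uptake units),
#' giving directed fluxes `vf = max(net, 0) + e`, `vb = max(-net, 0) + e`.
#'
#' @param net a [MetabolicNetwork]
#' @param n number of samples (`n = 0` gives an empty list)
#' @param seed integer seed; identical seeds give identical samples
#' @param uptake net id of the uptake reaction; default: the first
#'   reaction in model order consuming a substrate
#' @param ratioFlux net id whose flux ratio relative to uptake is recorded
#'   per sample (e.g. the phosphoketolase split); `NULL` for none
#' @return list of samples, each `list(fluxes, net, ratio)`: directed
#'   fluxes (ids like `v6f`/`v6b`), net fluxes by undirected id, and the
#'   requested flux ratio
#' @examples
#' xyl <- loadFixture("xylose")
#' s <- sampleFluxes(xyl, 3, seed = 1, ratioFlux = "v2")
#' vapply(s, `[[`, 0, "ratio")
#' @export
sampleFluxes <- function(net, n, seed, uptake = NULL, ratioFlux = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  stoich <- stoichiometricMatrix(net)
  if (is.null(uptake)) uptake <- .defaultUptake(net)
  if (!(uptake %in% stoich$reactions)) stop("unknown uptake id: ", uptake,
                                            call. = FALSE)
  if (!is.null(ratioFlux) && !(ratioFlux %in% stoich$reactions))
    stop("unknown ratio flux id: ", ratioFlux, call. = FALSE)

  S <- stoich$S
  rest <- setdiff(stoich$reactions, uptake)
  b <- -S[, uptake, drop = TRUE]
  Srest <- S[, rest, drop = FALSE]
  qrd <- qr(Srest)
  r <- qrd$rank
  dep <- rest[qrd$pivot[seq_len(r)]]
  free <- rest[qrd$pivot[-seq_len(r)]]
  qrdep <- qr(Srest[, dep, drop = FALSE])
  irrev <- stoich$reactions[!stoich$reversible]

  if (exists(".Random.seed", envir = globalenv())) {
    oldseed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldseed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  out <- vector("list", n)
  accepted <- 0L
  tries <- 0L
  maxtries <- max(10000L, 10000L * n)
  while (accepted < n) {
    tries <- tries + 1L
    if (tries > maxtries)
      stop("sampling error: could not find ", n,
           " non-negative steady states in ", maxtries,
           " draws (infeasible or tightly constrained network)",
           call. = FALSE)
    vfree <- runif(length(free))
    rhs <- b - if (length(free))
      Srest[, free, drop = FALSE] %*% vfree else 0
    vdep <- qr.coef(qrdep, rhs)
    v <- setNames(numeric(length(stoich$reactions)), stoich$reactions)
    v[uptake] <- 1
    v[dep] <- vdep
    v[free] <- vfree
    if (max(abs(S %*% v)) > 1e-8)
      stop("sampling error: mass balances are infeasible at uptake = 1",
           call. = FALSE)
    if (any(v[irrev] < -1e-10)) next
    v[irrev][v[irrev] < 0] <- 0
    directed <- numeric(0)
    for (id in stoich$reactions) {
      if (stoich$reversible[id]) {
        e <- 10^runif(1, -3, 1)
        directed[paste0(id, "f")] <- max(v[id], 0) + e
        directed[paste0(id, "b")] <- max(-v[id], 0) + e
      } else {
        directed[id] <- v[id]
      }
    }
    accepted <- accepted + 1L
    out[[accepted]] <- list(
      fluxes = directed, net = v,
      ratio = if (is.null(ratioFlux)) NA_real_
              else unname(v[ratioFlux] / v[uptake]))
  }
  out
}

#' Simulate a fractional-labeling panel over tracers and readouts
#'
#' Full factorial simulation: for every flux sample and every tracer, the
#' EMU cascade is solved once and the fractional labeling of every readout
#' EMU is recorded. The decomposition is performed (and reduced) once and
#' reused across samples; each sample's balance matrices are assembled
#' once and reused across tracers.
#'
#' @param net a [MetabolicNetwork]
#' @param tracers character vector of tracer spec strings (see
#'   [parseTracer()]); names are used as tracer ids
#' @param readouts character vector of readout EMU names
#' @param samples list of flux samples from [sampleFluxes()]
#' @param dec optional pre-built [EMUDecomposition] for `readouts`
#' @return data.frame with columns `sample`, `tracer`, `readout`, `fl`,
#'   `ratio`
#' @export
simulatePanel <- function(net, tracers, readouts, samples, dec = NULL) {
  if (is.null(names(tracers)))
    names(tracers) <- tracers
  if (is.null(dec))
    dec <- combineEquivalents(reduceUnimolecular(decomposeEMU(net, readouts)))
  parsed <- lapply(tracers, parseTracer, net = net)
  substrates <- boundaryMetabolites(buildMAM(net))$substrates
  rows <- vector("list", length(samples) * length(tracers))
  k <- 0L
  for (si in seq_along(samples)) {
    smp <- samples[[si]]
    systems <- lapply(dec@eams, assembleSystem, fluxes = smp$fluxes)
    for (ti in seq_along(parsed)) {
      res <- .runCascade(dec, systems, parsed[[ti]], substrates = substrates)
      fls <- vapply(readouts, function(e) fractionalLabeling(res[[e]]), 0)
      k <- k + 1L
      rows[[k]] <- data.frame(sample = si, tracer = names(tracers)[ti],
                              readout = readouts, fl = unname(fls),
                              ratio = smp$ratio, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank tracer/readout designs by correlation with the flux ratio
#'
#' For every (tracer, readout) pair the Spearman rank correlation between
#' fractional labeling and the flux ratio, and the ordinary least-squares
#' slope of FL regressed on the ratio, are computed over the samples.
#' Pairs whose FL is constant across samples carry no flux information
#' (e.g. a uniformly labeled tracer mixture); they are flagged, given
#' rho = slope = 0, and sorted to the bottom.
#'
#' @param panel data.frame from [simulatePanel()]
#' @return data.frame with columns `tracer`, `readout`, `spearman_rho`,
#'   `slope`, `n_samples`, `constant_fl`, sorted by |rho| then |slope|,
#'   descending, informative designs first
#' @export
rankDesigns <- function(panel) {
  stopifnot(all(c("tracer", "readout", "fl", "ratio") %in% names(panel)))
  groups <- unique(panel[c("tracer", "readout")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- panel[panel$tracer == groups$tracer[i] &
                 panel$readout == groups$readout[i], ]
    if (nrow(sub) < 3)
      stop("need at least 3 samples per design", call. = FALSE)
    const <- (max(sub$fl) - min(sub$fl)) < 1e-12
    if (const) {
      rho <- 0; slope <- 0
    } else {
      rho <- cor(sub$fl, sub$ratio, method = "spearman")
      slope <- unname(coef(lm(fl ~ ratio, data = sub))[2])
    }
    data.frame(tracer = groups$tracer[i], readout = groups$readout[i],
               spearman_rho = rho, slope = slope, n_samples = nrow(sub),
               constant_fl = const, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$constant_fl, -abs(out$spearman_rho),
                   -abs(out$slope)), ]
  rownames(out) <- NULL
  out
}

#' Estimate a flux ratio from measured fractional labeling
#'
#' Accept/reject estimation: flux samples whose simulated FL falls inside
#' `mean +/- tol` for every measured readout are accepted, and the flux
#' ratio is summarized as the mean and the 2.5th/97.5th percentiles of the
#' accepted samples' ratios, in percent of the uptake flux.
#'
#' @param panel data.frame from [simulatePanel()] simulated under the
#'   experimental tracer (a single tracer)
#' @param measurements data.frame with columns `readout`, `fl`, `tol` (or
#'   a named list `readout = c(fl, tol)`); `tol = Inf` disables filtering
#'   on that readout
#' @return list with `mean`, `ci_low`, `ci_high` (percent) and
#'   `n_accepted`
#' @examples
#' \dontrun{
#' est <- estimateFluxRatio(panel, data.frame(
#'   readout = c("AC_1", "AC_2", "AC_12"),
#'   fl = c(0.462, 0.469, 0.465), tol = c(0.018, 0.012, 0.015)))
#' }
#' @export
estimateFluxRatio <- function(panel, measurements) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- data.frame(
      readout = names(measurements),
      fl = vapply(measurements, `[[`, 0, 1),
      tol = vapply(measurements, `[[`, 0, 2), stringsAsFactors = FALSE)
  stopifnot(nrow(measurements) >= 1)
  if (length(unique(panel$tracer)) != 1)
    stop("panel must be simulated under a single experimental tracer",
         call. = FALSE)
  keep <- NULL
  for (i in seq_len(nrow(measurements))) {
    sub <- panel[panel$readout == measurements$readout[i], ]
    if (!nrow(sub))
      stop("readout ", measurements$readout[i], " absent from panel",
           call. = FALSE)
    ok <- sub$sample[abs(sub$fl - measurements$fl[i]) <= measurements$tol[i]]
    keep <- if (is.null(keep)) ok else intersect(keep, ok)
  }
  if (!length(keep))
    stop("estimation error: no simulated sample matches all measured FL ",
         "ranges; increase the sample count or widen the tolerances",
         call. = FALSE)
  ratios <- panel$ratio[match(keep, panel$sample)]
  list(mean = 100 * mean(ratios),
       ci_low = 100 * unname(quantile(ratios, 0.025)),
       ci_high = 100 * unname(quantile(ratios, 0.975)),
       n_accepted = length(keep))
}
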