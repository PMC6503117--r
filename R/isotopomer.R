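# Brute-force steady-state isotopomer simulator, used as an independent
# correctness oracle for the EMU cascade on small networks. A metabolite
# with n carbons has 2^n isotopomer states (bit k set = carbon k labeled).
# The steady-state balance for every non-substrate metabolite — total
# influx times its own distribution equals the influx-weighted mixture of
# source-pattern products — is bilinear when condensations join two
# unknown pools, so it is solved by damped Gauss-Seidel fixed-point
# iteration rather than one linear solve. Rotational symmetry is handled
# by orientation averaging of the atom maps, exactly as in the EMU code
# path but implemented independently of it.

.bitAt <- function(x, k) bitwAnd(bitwShiftR(x, k - 1L), 1L)

# one production channel: Agg %*% kron(reactant isotopomer vectors)
# gives the isotopomer distribution this (reaction, product instance)
# feeds into the product pool. Variants are folded into one sparse matrix.
.buildChannel <- function(net, reaction, prod_instance) {
  variants <- .reactionVariants(net, reaction)
  rmets <- vapply(reaction$reactants, `[[`, "", "met")
  rn <- vapply(rmets, function(m) net@metabolites[[m]]$n, 0)
  offsets <- cumsum(c(0, rn))[seq_along(rn)]
  N <- as.integer(2^sum(rn))
  pm <- reaction$products[[prod_instance]]$met
  np <- net@metabolites[[pm]]$n
  states <- 0:(N - 1L)
  trip_i <- integer(0); trip_x <- numeric(0)
  Agg <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(2^np, N))
  for (var in variants) {
    ratoms <- lapply(var$reactants, function(t) strsplit(t$atoms, "")[[1]])
    patoms <- strsplit(var$products[[prod_instance]]$atoms, "")[[1]]
    pattern <- integer(N)
    for (j in seq_len(np)) {
      letter <- patoms[j]
      hit <- NULL
      for (ri in seq_along(ratoms)) {
        p <- which(ratoms[[ri]] == letter)
        if (length(p)) { hit <- c(ri, p); break }
      }
      if (is.null(hit)) next  # carbon sourced outside the model: impossible
      sri <- bitwAnd(bitwShiftR(states, offsets[hit[1]]),
                     as.integer(2^rn[hit[1]] - 1))
      pattern <- pattern + .bitAt(sri, hit[2]) * as.integer(2^(j - 1))
    }
    Agg <- Agg + Matrix::sparseMatrix(i = pattern + 1L, j = states + 1L,
                                      x = var$weight, dims = c(2^np, N))
  }
  # dense base matrix: channels are small (<= 2^7 x 2^10 here) and dense
  # matmul avoids per-sweep S4 dispatch overhead in the iteration loop
  list(rmets = rmets, Agg = as.matrix(Agg))
}

#' Steady-state isotopomer distributions (brute force)
#'
#' Solves the full isotopomer balance of a network by damped Gauss-Seidel
#' fixed-point iteration: every non-substrate metabolite's distribution is
#' repeatedly replaced by the influx-weighted mixture of its production
#' channels until the largest change falls below `tol`. Intended as an
#' independent oracle for [solveCascade()] on networks whose metabolites
#' have at most 12 carbons.
#'
#' @param net a [MetabolicNetwork]
#' @param fluxes named numeric vector of non-negative directed fluxes
#' @param tracer tracer spec string(s) or parsed tracer
#' @param tol convergence tolerance on the max absolute change per sweep
#' @param maxit maximum number of sweeps
#' @param damp damping factor in (0, 1]; 1 = plain Gauss-Seidel
#' @return named list: metabolite -> numeric vector of length 2^n with
#'   isotopomer fractions (substrates included, fixed by the tracer)
#' @seealso [marginalizeIsotopomers()]
#' @export
simulateIsotopomers <- function(net, fluxes, tracer, tol = 1e-12,
                                maxit = 1e5, damp = 1) {
  validObject(net)
  if (is.character(tracer)) tracer <- parseTracer(tracer, net)
  for (m in net@metabolites)
    if (m$n > 12)
      stop("isotopomer oracle limited to metabolites with <= 12 carbons",
           call. = FALSE)
  substrates <- boundaryMetabolites(buildMAM(net))$substrates

  iso <- list()
  for (m in net@metabolites) {
    v <- numeric(2^m$n)
    if (m$name %in% substrates) {
      species <- tracer[[m$name]]
      if (is.null(species))
        species <- list(list(positions = integer(0), fraction = 1))
      for (sp in species) {
        idx <- sum(2^(sp$positions - 1)) + 1
        v[idx] <- v[idx] + sp$fraction
      }
    } else {
      v[1] <- 1
    }
    iso[[m$name]] <- v
  }

  channels <- list()  # per internal metabolite
  for (r in net@reactions) {
    for (pi in seq_along(r$products)) {
      pm <- r$products[[pi]]$met
      if (pm %in% substrates) next
      ch <- .buildChannel(net, r, pi)
      ch$flux <- r$id
      channels[[pm]] <- c(channels[[pm]], list(ch))
    }
  }

  internal <- setdiff(names(net@metabolites), substrates)
  for (m in internal)
    if (is.null(channels[[m]]))
      stop("metabolite ", m, " is internal but never produced", call. = FALSE)

  # resolve flux rates once; drop zero-rate channels before iterating
  active <- list()
  for (m in internal) {
    chs <- list()
    tot <- 0
    for (ch in channels[[m]]) {
      if (!(ch$flux %in% names(fluxes)))
        stop("missing flux value: ", ch$flux, call. = FALSE)
      v <- unname(fluxes[ch$flux])
      if (v == 0) next
      ch$rate <- v
      chs <- c(chs, list(ch))
      tot <- tot + v
    }
    if (tot == 0)
      stop("oracle failure: zero total influx to ", m, call. = FALSE)
    active[[m]] <- list(channels = chs, tot = tot)
  }

  delta <- Inf
  for (it in seq_len(maxit)) {
    delta <- 0
    for (m in internal) {
      a <- active[[m]]
      mix <- 0
      for (ch in a$channels) {
        kron <- if (length(ch$rmets) == 1L) iso[[ch$rmets]]
                else Reduce(function(x, y) as.vector(outer(x, y)),
                            lapply(ch$rmets, function(x) iso[[x]]))
        mix <- mix + ch$rate * (ch$Agg %*% kron)
      }
      new <- mix / a$tot
      # bilinear condensation terms square any unit-sum drift each sweep;
      # renormalizing keeps round-off from compounding
      new <- new / sum(new)
      if (damp < 1) new <- damp * new + (1 - damp) * iso[[m]]
      delta <- max(delta, max(abs(new - iso[[m]])))
      iso[[m]] <- as.numeric(new)
    }
    if (delta < tol) return(iso)
  }
  stop("oracle failure: no convergence after ", maxit,
       " sweeps (residual ", format(delta), ")", call. = FALSE)
}

#' Marginalize an isotopomer distribution onto an EMU
#'
#' MDV entry i is the total fraction of isotopomer patterns carrying
#' exactly i labels among the EMU's atom positions.
#'
#' @param iso result of [simulateIsotopomers()]
#' @param emu EMU name
#' @return numeric MDV of length size+1
#' @export
marginalizeIsotopomers <- function(iso, emu) {
  e <- parseEMU(emu)
  v <- iso[[e$met]]
  if (is.null(v))
    stop("metabolite ", e$met, " absent from isotopomer result",
         call. = FALSE)
  states <- 0:(length(v) - 1L)
  k <- integer(length(v))
  for (p in e$atoms) k <- k + .bitAt(states, p)
  mdv <- numeric(e$size + 1)
  for (i in 0:e$size) mdv[i + 1] <- sum(v[k == i])
  mdv
}
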