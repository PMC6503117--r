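# Cascaded EMU balance assembly and solution.
#
# For each size i the reduced EAM yields A_i X_i = B_i Y_i with X_i the
# unknown MDVs (rows) and Y_i the known source MDVs: substrate EMUs and
# convolutions of previously solved smaller EMUs. A_i is the transpose of
# the upper square submatrix of the EAM after its diagonal is set to the
# negative total influx of each column; B_i is the transpose of the lower
# submatrix with entries negated.

#' Parse a tracer specification string
#'
#' Grammar per substrate: `NAME:positions@fraction[,positions@fraction...]`
#' where `positions` is a digit string of labeled 1-based carbon positions,
#' `U` labels all positions and `0` labels none. Fractions must not exceed
#' 1; a shortfall is completed with unlabeled substrate. Substrates not
#' mentioned are unlabeled.
#'
#' @param spec character vector, one entry per substrate, e.g.
#'   `"Xyl:12@1.0"` or `c("Xyl:U@0.5,0@0.5", "Glc:1@1")`
#' @param net optional [MetabolicNetwork] used to validate positions
#' @return named list: substrate -> list of `list(positions, fraction)`
#' @examples
#' parseTracer("Xyl:12@1.0")
#' @export
parseTracer <- function(spec, net = NULL) {
  out <- list()
  for (s in spec) {
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*):(.+)$", s))[[1]]
    if (length(m) != 3)
      stop("cannot parse tracer spec '", s, "'", call. = FALSE)
    met <- m[2]
    n <- if (!is.null(net)) net@metabolites[[met]]$n else NULL
    species <- list()
    total <- 0
    for (piece in strsplit(m[3], ",")[[1]]) {
      pm <- regmatches(piece, regexec("^(U|0|[1-9]+)@([0-9.eE+-]+)$",
                                      trimws(piece)))[[1]]
      if (length(pm) != 3)
        stop("cannot parse tracer component '", piece, "'", call. = FALSE)
      pos <- if (pm[2] == "U") {
        if (is.null(n))
          stop("tracer 'U' requires a network to resolve the carbon count",
               call. = FALSE)
        seq_len(n)
      } else if (pm[2] == "0") integer(0)
      else as.integer(strsplit(pm[2], "")[[1]])
      frac <- as.numeric(pm[3])
      if (is.na(frac) || frac < 0)
        stop("bad tracer fraction in '", piece, "'", call. = FALSE)
      if (!is.null(n) && any(pos > n))
        stop("tracer position out of range for ", met, call. = FALSE)
      species <- c(species, list(list(positions = pos, fraction = frac)))
      total <- total + frac
    }
    if (total > 1 + 1e-9)
      stop("tracer fractions for ", met, " exceed 1", call. = FALSE)
    if (total < 1 - 1e-9)
      species <- c(species, list(list(positions = integer(0),
                                     fraction = 1 - total)))
    out[[met]] <- species
  }
  out
}

#' MDV of a substrate EMU under a tracer specification
#'
#' Entry i of the result is the total molar fraction of tracer species
#' carrying exactly i labeled atoms among the EMU's positions. Substrates
#' absent from the tracer are unlabeled.
#'
#' @param net a [MetabolicNetwork]
#' @param tracer parsed tracer (see [parseTracer()]) or spec string(s)
#' @param emu substrate EMU name
#' @return numeric MDV of length size+1
#' @examples
#' net <- loadFixture("xylose")
#' substrateMDV(net, "Xyl:12@1.0", "Xyl_12")  # c(0, 0, 1)
#' @export
substrateMDV <- function(net, tracer, emu) {
  if (is.character(tracer)) tracer <- parseTracer(tracer, net)
  e <- .checkEMU(net, emu)
  species <- tracer[[e$met]]
  if (is.null(species))
    species <- list(list(positions = integer(0), fraction = 1))
  mdv <- numeric(e$size + 1)
  for (sp in species) {
    if (any(sp$positions > net@metabolites[[e$met]]$n))
      stop("tracer position out of range for ", e$met, call. = FALSE)
    k <- sum(e$atoms %in% sp$positions)
    mdv[k + 1] <- mdv[k + 1] + sp$fraction
  }
  mdv
}

#' Convolve two mass distribution vectors
#'
#' Cauchy product: the MDV of a molecule condensed from two precursor
#' fragments. Commutative; preserves the unit sum.
#'
#' @param a,b numeric MDVs
#' @return numeric MDV of length `length(a) + length(b) - 1`
#' @examples
#' convolveMDV(c(0.5, 0.5), c(0.5, 0.5))  # c(0.25, 0.5, 0.25)
#' @export
convolveMDV <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}

#' Fractional labeling of an MDV
#'
#' FL = (sum_i i * m_i) / n for an EMU of n carbons: the average fraction
#' of labeled carbons.
#'
#' @param mdv numeric MDV of length n+1, n >= 1
#' @return FL in `[0, 1]`
#' @export
fractionalLabeling <- function(mdv) {
  n <- length(mdv) - 1
  if (n < 1) stop("fractional labeling is undefined for a size-0 MDV",
                  call. = FALSE)
  sum(seq(0, n) * mdv) / n
}

#' Assemble the numeric balance system of one EAM
#'
#' Applies the transposition rule: the EAM diagonal is set to the negative
#' flux-weighted column sum (total influx of each unknown EMU); `A` is the
#' transpose of the upper square submatrix and `B` the transpose of the
#' lower (known-row) submatrix with entries negated, so that
#' `A %*% X = B %*% Y`.
#'
#' @param eam an [EAM]
#' @param fluxes named numeric vector covering every flux id in the EAM
#' @return list with `A` (k x k), `B` (k x m), `unknowns`, `knowns`
#' @export
assembleSystem <- function(eam, fluxes) {
  e <- eam@entries
  missing <- setdiff(unique(e$flux), names(fluxes))
  if (length(missing))
    stop("missing flux value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  k <- length(eam@columns)
  m <- length(eam@knowns)
  vals <- e$coeff * as.numeric(fluxes[e$flux])
  ci <- match(e$col, eam@columns)
  U <- matrix(0, k, k, dimnames = list(eam@columns, eam@columns))
  L <- matrix(0, m, k, dimnames = list(eam@knowns, eam@columns))
  upper <- e$row %in% eam@columns
  if (any(upper)) {
    idx <- cbind(match(e$row[upper], eam@columns), ci[upper])
    for (j in seq_len(sum(upper)))
      U[idx[j, 1], idx[j, 2]] <- U[idx[j, 1], idx[j, 2]] + vals[upper][j]
  }
  if (any(!upper)) {
    idx <- cbind(match(e$row[!upper], eam@knowns), ci[!upper])
    for (j in seq_len(sum(!upper)))
      L[idx[j, 1], idx[j, 2]] <- L[idx[j, 1], idx[j, 2]] + vals[!upper][j]
  }
  agg <- rowsum(vals, ci)  # total influx per column
  infl <- numeric(k)
  infl[as.integer(rownames(agg))] <- agg[, 1]
  diag(U) <- diag(U) - infl
  list(A = t(U), B = -t(L), unknowns = eam@columns, knowns = eam@knowns)
}

.resolveName <- function(name, equiv) {
  if (length(equiv) && name %in% names(equiv)) unname(equiv[name]) else name
}

# MDV of a known row term given substrate labeling and solved smaller EMUs
.termMDV <- function(term, net, tracer, solved, equiv, substrates) {
  parts <- lapply(.termFactors(term), function(f) {
    fm <- parseEMU(f)$met
    if (fm %in% substrates) return(substrateMDV(net, tracer, f))
    f <- .resolveName(f, equiv)
    v <- solved[[f]]
    if (is.null(v))
      stop("cascade error: MDV of '", f, "' needed before it is solved",
           call. = FALSE)
    v
  })
  Reduce(convolveMDV, parts)
}

#' Solve the EMU cascade and simulate MDVs
#'
#' Solves the per-size balance systems in ascending size order,
#' `X_i = A_i^-1 B_i Y_i`, with `Y_i` assembled from substrate EMU MDVs
#' (given by the tracer), previously solved MDVs and their convolutions.
#' Works on raw, reduced, or reduced-and-combined decompositions and gives
#' identical target MDVs in all three cases.
#'
#' @param dec an [EMUDecomposition]
#' @param fluxes named numeric vector of non-negative fluxes covering all
#'   reactions of the decomposition (directed ids, e.g. `v6f`, `v6b`)
#' @param tracer tracer spec string(s) or parsed tracer ([parseTracer()])
#' @return an [MDVSet] with one MDV per unknown EMU (plus any target that
#'   is itself a substrate EMU)
#' @examples
#' tca <- loadFixture("tca")
#' dec <- combineEquivalents(reduceUnimolecular(decomposeEMU(tca, "Glu_12345")))
#' fl <- c(v1 = 1, v2 = 1, v3 = 0.5, v4 = 0.5, v5 = 0.5,
#'         v6f = 0.5, v6b = 0, v7 = 0.5)
#' res <- solveCascade(dec, fl, "AcCoA:12@0.5,0@0.5")
#' res[["Glu_12345"]]
#' @export
solveCascade <- function(dec, fluxes, tracer) {
  systems <- lapply(dec@eams, assembleSystem, fluxes = fluxes)
  .runCascade(dec, systems, tracer)
}

# cascade solution given pre-assembled numeric systems (one per size);
# lets panel simulation reuse a sample's A/B matrices across tracers
.runCascade <- function(dec, systems, tracer, substrates = NULL) {
  net <- dec@network
  if (is.character(tracer)) tracer <- parseTracer(tracer, net)
  if (is.null(substrates))
    substrates <- boundaryMetabolites(buildMAM(net))$substrates
  solved <- list()
  sizes <- sort(as.integer(names(dec@eams)))
  for (s in sizes) {
    eam <- dec@eams[[as.character(s)]]
    if (!length(eam@columns)) next
    sys <- systems[[as.character(s)]]
    Y <- do.call(rbind, lapply(sys$knowns, .termMDV, net = net,
                               tracer = tracer, solved = solved,
                               equiv = dec@equivalents,
                               substrates = substrates))
    if (is.null(Y)) Y <- matrix(0, 0, s + 1)
    X <- tryCatch(solve(sys$A, sys$B %*% Y), error = function(err)
      stop("singular EMU balance of size ", s,
           " (zero-influx or disconnected EMU among: ",
           paste(sys$unknowns, collapse = ", "), ")", call. = FALSE))
    if (min(X) < -1e-9)
      stop("numerical-consistency error: negative MDV entry ",
           format(min(X)), " at size ", s, call. = FALSE)
    X[X < 0] <- 0
    X <- X / rowSums(X)
    for (i in seq_along(sys$unknowns))
      solved[[sys$unknowns[i]]] <- as.numeric(X[i, ])
  }
  for (t in dec@targets) {
    if (parseEMU(t)$met %in% substrates && is.null(solved[[t]]))
      solved[[t]] <- substrateMDV(net, tracer, t)
  }
  new("MDVSet", mdvs = solved, equivalents = dec@equivalents)
}
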