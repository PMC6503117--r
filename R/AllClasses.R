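#' @import methods
#' @importFrom stats runif quantile cor coef lm setNames
#' @importFrom utils write.csv head
NULL

#' Atom-mapped metabolic network
#'
#' Container for a carbon atom-mapped metabolic network. Metabolites carry a
#' carbon count and, optionally, a rotational-symmetry permutation (a
#' self-inverse bijection of 1-based carbon positions, e.g. the 1-4/2-3 axis
#' of fumarate). Reactions are directed; a reversible reaction in a model
#' file is represented as a forward/backward pair with mirrored atom maps.
#'
#' @slot metabolites named list, one entry per metabolite: a list with
#'   elements \code{name}, \code{n} (carbon count) and \code{sym}
#'   (integer permutation of \code{1:n}, or \code{NULL}).
#' @slot reactions ordered list of reactions; each is a list with elements
#'   \code{id}, \code{base} (undirected id), \code{dir} (\code{""},
#'   \code{"f"} or \code{"b"}), \code{reversible} (logical) and
#'   \code{reactants}/\code{products}, lists of terms
#'   \code{list(met, atoms)} where \code{atoms} is a string of distinct
#'   lowercase letters, position k being the label of carbon k.
#'
#' @seealso [parseModel()], [buildMAM()], [decomposeEMU()]
#' @export
setClass("MetabolicNetwork",
  representation(metabolites = "list", reactions = "list"))

setValidity("MetabolicNetwork", function(object) {
  msgs <- character()
  mets <- object@metabolites
  for (m in mets) {
    if (!is.numeric(m$n) || m$n < 0)
      msgs <- c(msgs, sprintf("metabolite %s: negative carbon count", m$name))
    if (!is.null(m$sym)) {
      p <- m$sym
      if (length(p) != m$n || !setequal(p, seq_len(m$n)) ||
          !identical(p[p], seq_len(as.integer(m$n))))
        msgs <- c(msgs, sprintf(
          "metabolite %s: symmetry must be a self-inverse permutation of 1..%d",
          m$name, m$n))
    }
  }
  ids <- vapply(object@reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate flux id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (r in object@reactions) {
    for (term in c(r$reactants, r$products)) {
      if (is.null(mets[[term$met]]))
        msgs <- c(msgs, sprintf("reaction %s references undeclared metabolite %s",
                                r$id, term$met))
      else if (nchar(term$atoms) != mets[[term$met]]$n)
        msgs <- c(msgs, sprintf(
          "reaction %s: atom string for %s has length %d, expected %d",
          r$id, term$met, nchar(term$atoms), mets[[term$met]]$n))
    }
    rl <- unlist(strsplit(vapply(r$reactants, `[[`, "", "atoms"), ""))
    pl <- unlist(strsplit(vapply(r$products, `[[`, "", "atoms"), ""))
    if (anyDuplicated(rl) || anyDuplicated(pl))
      msgs <- c(msgs, sprintf("reaction %s: repeated atom letter within a side", r$id))
    if (!all(pl %in% rl))
      msgs <- c(msgs, sprintf("reaction %s: carbon-balance error, product atom(s) %s unsourced",
                              r$id, paste(setdiff(pl, rl), collapse = ",")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Metabolite adjacency matrix (MAM)
#'
#' Square matrix over the metabolites of a network. Cell (r, c) holds the
#' ids of the reactions converting row metabolite r into column metabolite
#' c. Substrates are the metabolites whose column is empty (nothing
#' produces them); final products are those whose row is empty.
#'
#' @slot index ordered metabolite names (rows and columns).
#' @slot cells list-matrix; each cell a character vector of flux ids.
#' @seealso [buildMAM()], [boundaryMetabolites()]
#' @export
setClass("MAM", representation(index = "character", cells = "matrix"))

setValidity("MAM", function(object) {
  d <- dim(object@cells)
  if (d[1] != d[2] || d[1] != length(object@index))
    return("MAM must be square with one row/column per metabolite")
  TRUE
})

#' EMU adjacency matrix (EAM) for one EMU size
#'
#' Flux-weighted adjacency matrix over EMUs of a single size. Columns are
#' the unknown EMUs of this size; rows are the columns' EMUs followed by
#' known source terms (substrate EMUs and convolution products of smaller
#' EMUs, written \code{"A_12*B_3"}). Entries are stored as a triplet table
#' (row term, column EMU, flux id, coefficient); coefficients below 1
#' arise from rotational-symmetry orientation averaging.
#'
#' @slot size EMU size (number of carbons).
#' @slot columns unknown EMU names of this size.
#' @slot knowns known row terms (substrate EMUs first, then convolutions).
#' @slot entries data.frame with columns \code{row}, \code{col},
#'   \code{flux}, \code{coeff}.
#' @export
setClass("EAM", representation(size = "integer", columns = "character",
                               knowns = "character", entries = "data.frame"))

setValidity("EAM", function(object) {
  e <- object@entries
  if (!all(c("row", "col", "flux", "coeff") %in% names(e)))
    return("entries must have columns row, col, flux, coeff")
  if (nrow(e) && !all(e$col %in% object@columns))
    return("entries reference unknown columns")
  if (length(object@columns) && !all(object@columns %in% e$col))
    return("every column EMU must have at least one incoming entry")
  if (any(object@knowns %in% object@columns))
    return("known rows may not appear as columns")
  if (nrow(e) && any(e$coeff <= 0))
    return("coefficients must be positive")
  TRUE
})

#' Size-stratified EMU decomposition of a network
#'
#' Result of breadth-first EMU decomposition from a set of target EMUs:
#' one [EAM] per EMU size, plus bookkeeping needed to solve the cascade
#' (the parent network, the targets, and the equivalence map filled in by
#' [combineEquivalents()]).
#'
#' @slot eams list of [EAM] objects, named by size, ascending.
#' @slot targets target EMU names.
#' @slot network the parent [MetabolicNetwork].
#' @slot equivalents named character vector mapping each EMU to the
#'   representative of its rotational-equivalence class (identity before
#'   [combineEquivalents()] is applied).
#' @slot reduced,combined logicals recording which reductions were applied.
#' @seealso [decomposeEMU()], [reduceUnimolecular()], [combineEquivalents()],
#'   [countVariables()], [solveCascade()]
#' @export
setClass("EMUDecomposition",
  representation(eams = "list", targets = "character",
                 network = "MetabolicNetwork", equivalents = "character",
                 reduced = "logical", combined = "logical"))

#' Solved mass distribution vectors for a set of EMUs
#'
#' Named collection of MDVs (numeric vectors of length size+1, entry i+1 =
#' fractional abundance of the M+i isotopologue) returned by
#' [solveCascade()]. Indexing with \code{[[} resolves rotationally
#' equivalent EMU names to their class representative.
#'
#' @slot mdvs named list of numeric MDVs.
#' @slot equivalents named character vector resolving equivalent EMU names.
#' @export
setClass("MDVSet", representation(mdvs = "list", equivalents = "character"))

setMethod("show", "MetabolicNetwork", function(object) {
  bnd <- tryCatch(boundaryMetabolites(buildMAM(object)),
                  error = function(e) NULL)
  cat(sprintf("MetabolicNetwork: %d metabolites, %d reactions\n",
              length(object@metabolites), length(object@reactions)))
  nsym <- sum(!vapply(object@metabolites, function(m) is.null(m$sym), TRUE))
  if (nsym) cat(sprintf("  symmetric metabolites: %s\n",
    paste(names(object@metabolites)[!vapply(object@metabolites,
      function(m) is.null(m$sym), TRUE)], collapse = ", ")))
  if (!is.null(bnd)) {
    cat("  substrates:", paste(bnd$substrates, collapse = ", "), "\n")
    cat("  products:  ", paste(bnd$products, collapse = ", "), "\n")
  }
})

setMethod("show", "MAM", function(object) {
  cat(sprintf("MAM: %d x %d metabolites\n", length(object@index),
              length(object@index)))
  n <- sum(lengths(object@cells) > 0)
  cat(sprintf("  %d non-empty cells\n", n))
})

setMethod("show", "EAM", function(object) {
  cat(sprintf("EAM size %d: %d unknown EMUs, %d known rows, %d entries\n",
              object@size, length(object@columns), length(object@knowns),
              nrow(object@entries)))
})

setMethod("show", "EMUDecomposition", function(object) {
  cat(sprintf("EMUDecomposition: targets %s\n",
              paste(object@targets, collapse = ", ")))
  for (e in object@eams)
    cat(sprintf("  size %d: %d unknowns\n", e@size, length(e@columns)))
  cat(sprintf("  reduced: %s, equivalents combined: %s; %d EMU variables\n",
              object@reduced, object@combined, countVariables(object)))
})

setMethod("show", "MDVSet", function(object) {
  cat(sprintf("MDVSet: %d EMUs\n", length(object@mdvs)))
  for (nm in head(names(object@mdvs), 8))
    cat(sprintf("  %-14s [%s]  FL=%.4f\n", nm,
                paste(sprintf("%.4f", object@mdvs[[nm]]), collapse = ", "),
                fractionalLabeling(object@mdvs[[nm]])))
  if (length(object@mdvs) > 8) cat("  ...\n")
})

#' @describeIn MDVSet number of solved EMUs
#' @param x an \code{MDVSet}
#' @export
setMethod("length", "MDVSet", function(x) length(x@mdvs))

#' @describeIn MDVSet solved EMU names
#' @export
setMethod("names", "MDVSet", function(x) names(x@mdvs))

#' @describeIn MDVSet extract one MDV by EMU name (equivalent EMU names
#'   resolve to their class representative)
#' @param i EMU name
#' @export
setMethod("[[", "MDVSet", function(x, i) {
  if (is.character(i) && !is.null(x@equivalents[i]) && !is.na(x@equivalents[i]))
    i <- unname(x@equivalents[i])
  out <- x@mdvs[[i]]
  if (is.null(out))
    stop("no MDV solved for EMU '", i, "'", call. = FALSE)
  out
})

#' EMUs solved in an MDVSet, as a data.frame
#'
#' @param x an [MDVSet]
#' @return data.frame with one row per EMU: name, mass isotopologue
#'   fractions \code{m0..mk} (NA-padded to the largest size) and
#'   fractional labeling \code{fl}.
#' @export
mdvTable <- function(x) {
  stopifnot(is(x, "MDVSet"))
  kmax <- max(lengths(x@mdvs))
  rows <- lapply(names(x@mdvs), function(nm) {
    v <- x@mdvs[[nm]]
    c(list(emu = nm),
      as.list(c(v, rep(NA_real_, kmax - length(v)))),
      list(fl = fractionalLabeling(v)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
    col.names = c("emu", paste0("m", seq_len(kmax) - 1), "fl"))))
  out
}
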