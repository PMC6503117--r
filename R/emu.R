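# EMU decomposition on the adjacency-matrix representation.
#
# An EMU is named "Met_ijk": metabolite plus strictly ascending 1-based
# carbon positions (so position digits require n_atoms <= 9; both fixture
# networks top out at 7 carbons). A convolution term, the source of a
# condensation product, is the '*'-joined product of its factor EMUs with
# factors in lexicographic order.

#' Construct / deconstruct canonical EMU names
#'
#' @param met metabolite name
#' @param atoms integer vector of 1-based carbon positions
#' @return `emuName`: the canonical name `Met_ijk`; `parseEMU`: a list
#'   with `met`, `atoms` (sorted), `size`.
#' @examples
#' emuName("OAA", c(4, 2, 3))
#' parseEMU("Glu_12345")
#' @export
emuName <- function(met, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  if (any(atoms > 9))
    stop("EMU naming supports at most 9 carbons per metabolite", call. = FALSE)
  paste0(met, "_", paste(atoms, collapse = ""))
}

#' @rdname emuName
#' @param name an EMU name such as `"OAA_234"`
#' @export
parseEMU <- function(name) {
  m <- regmatches(name, regexec("^(.*)_([1-9]+)$", name))[[1]]
  if (length(m) != 3)
    stop("not a valid EMU name: '", name, "'", call. = FALSE)
  atoms <- as.integer(strsplit(m[3], "")[[1]])
  if (anyDuplicated(atoms) || is.unsorted(atoms, strictly = TRUE))
    stop("EMU atom positions must be strictly ascending in '", name, "'",
         call. = FALSE)
  list(met = m[2], atoms = atoms, size = length(atoms))
}

.checkEMU <- function(net, name) {
  e <- parseEMU(name)
  m <- net@metabolites[[e$met]]
  if (is.null(m))
    stop("EMU '", name, "' references unknown metabolite", call. = FALSE)
  if (any(e$atoms > m$n))
    stop("EMU '", name, "' atom positions exceed the ", m$n,
         " carbons of ", e$met, call. = FALSE)
  e
}

.termFactors <- function(term) strsplit(term, "*", fixed = TRUE)[[1]]
.termString <- function(factors) paste(sort(factors), collapse = "*")
.termSize <- function(term, cache = NULL)
  sum(vapply(.termFactors(term), function(f) parseEMU(f)$size, 0L))

# All orientation variants of a reaction's atom maps: for every term whose
# metabolite carries a symmetry permutation, both the declared map and the
# map with that term's positions permuted are physically indistinguishable.
# Returns list of list(reactants, products, weight); weights sum to 1.
.reactionVariants <- function(net, reaction) {
  terms <- c(reaction$reactants, reaction$products)
  nR <- length(reaction$reactants)
  symidx <- which(vapply(terms, function(t)
    !is.null(net@metabolites[[t$met]]$sym), TRUE))
  if (!length(symidx))
    return(list(list(reactants = reaction$reactants,
                     products = reaction$products, weight = 1)))
  choices <- expand.grid(rep(list(c(FALSE, TRUE)), length(symidx)))
  w <- 1 / nrow(choices)
  out <- vector("list", nrow(choices))
  for (v in seq_len(nrow(choices))) {
    tv <- terms
    for (k in seq_along(symidx)) {
      if (!choices[v, k]) next
      i <- symidx[k]
      perm <- net@metabolites[[tv[[i]]$met]]$sym
      s <- strsplit(tv[[i]]$atoms, "")[[1]]
      tv[[i]]$atoms <- paste(s[perm], collapse = "")
    }
    out[[v]] <- list(reactants = tv[seq_len(nR)],
                     products = tv[-seq_len(nR)], weight = w)
  }
  out
}

#' Precursor EMU terms of an EMU through one reaction
#'
#' Traces each atom of `emu` back through the reaction's atom map. Atoms
#' landing in k distinct reactant instances yield a k-factor convolution
#' term. For rotationally symmetric metabolites both indistinguishable
#' orientations of the atom map are enumerated, each weighted by one over
#' the number of orientation variants, so the returned coefficients always
#' sum to the number of product instances of the EMU's metabolite.
#'
#' @param net a [MetabolicNetwork]
#' @param emu EMU name (e.g. `"Cit_12345"`)
#' @param reaction a reaction of `net` (element of `reactions(net)`) or a
#'   flux id
#' @return list of `list(factors, coeff)`; `factors` is the character
#'   vector of factor EMU names (sorted), `coeff` the positive weight.
#' @examples
#' tca <- loadFixture("tca")
#' emuPrecursors(tca, "Glu_12345", "v3")
#' emuPrecursors(tca, "Cit_12345", "v1")
#' @export
emuPrecursors <- function(net, emu, reaction) {
  if (is.character(reaction)) {
    ids <- vapply(net@reactions, `[[`, "", "id")
    reaction <- net@reactions[[match(reaction, ids)]]
    if (is.null(reaction)) stop("unknown flux id", call. = FALSE)
  }
  e <- .checkEMU(net, emu)
  prod_idx <- which(vapply(reaction$products, function(t) t$met == e$met, TRUE))
  if (!length(prod_idx))
    stop("EMU '", emu, "' is not a product of reaction ", reaction$id,
         call. = FALSE)
  acc <- list()
  for (var in .reactionVariants(net, reaction)) {
    ratoms <- lapply(var$reactants, function(t) strsplit(t$atoms, "")[[1]])
    for (pi in prod_idx) {
      patoms <- strsplit(var$products[[pi]]$atoms, "")[[1]]
      hits <- list()  # reactant instance -> positions
      for (p in e$atoms) {
        letter <- patoms[p]
        found <- FALSE
        for (ri in seq_along(ratoms)) {
          pos <- which(ratoms[[ri]] == letter)
          if (length(pos)) {
            key <- as.character(ri)
            hits[[key]] <- c(hits[[key]], pos)
            found <- TRUE
            break
          }
        }
        if (!found)
          stop("model inconsistency: atom ", p, " of ", emu,
               " unmapped in reaction ", reaction$id, call. = FALSE)
      }
      factors <- sort(unname(vapply(names(hits), function(ri)
        emuName(var$reactants[[as.integer(ri)]]$met, hits[[ri]]), "")))
      key <- .termString(factors)
      if (is.null(acc[[key]]))
        acc[[key]] <- list(factors = factors, coeff = 0)
      acc[[key]]$coeff <- acc[[key]]$coeff + var$weight
    }
  }
  unname(acc)
}

.aggregateEntries <- function(e) {
  if (!nrow(e)) return(e)
  key <- paste(e$row, e$col, e$flux, sep = "\r")
  agg <- rowsum(e$coeff, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(row = vapply(parts, `[[`, "", 1),
             col = vapply(parts, `[[`, "", 2),
             flux = vapply(parts, `[[`, "", 3),
             coeff = as.numeric(agg), stringsAsFactors = FALSE)
}

.buildEAM <- function(size, columns, entries) {
  rows <- unique(entries$row)
  single <- rows[!grepl("*", rows, fixed = TRUE)]
  knowns <- c(setdiff(single, columns),
              rows[grepl("*", rows, fixed = TRUE)])
  new("EAM", size = as.integer(size), columns = columns,
      knowns = knowns, entries = entries)
}

#' Decompose a network into size-stratified EMU adjacency matrices
#'
#' Breadth-first traversal from the target EMUs: each EMU's precursors are
#' found through every reaction producing its metabolite; factors of
#' condensation (convolution) terms become new start points of their own
#' sizes; traversal stops at substrate EMUs. Discovered EMU reactions are
#' collected into one [EAM] per size.
#'
#' @param net a [MetabolicNetwork]
#' @param targets character vector of target EMU names
#' @return an [EMUDecomposition]
#' @examples
#' tca <- loadFixture("tca")
#' dec <- decomposeEMU(tca, "Glu_12345")
#' countVariables(dec)  # 24 EMU variables before reduction
#' @seealso [reduceUnimolecular()], [combineEquivalents()], [solveCascade()]
#' @export
decomposeEMU <- function(net, targets) {
  validObject(net)
  bnd <- boundaryMetabolites(buildMAM(net))
  for (t in targets) .checkEMU(net, t)
  queue <- targets[!vapply(targets, function(t)
    parseEMU(t)$met %in% bnd$substrates, TRUE)]
  queue <- unique(queue)
  visited <- character()
  entries <- data.frame(row = character(), col = character(),
                        flux = character(), coeff = numeric(),
                        stringsAsFactors = FALSE)
  while (length(queue)) {
    emu <- queue[[1]]
    queue <- queue[-1]
    if (emu %in% visited) next
    visited <- c(visited, emu)
    e <- parseEMU(emu)
    producing <- Filter(function(r)
      any(vapply(r$products, function(t) t$met == e$met, TRUE)),
      net@reactions)
    if (!length(producing))
      stop("decomposition error: EMU '", emu,
           "' is unreachable (no reaction produces ", e$met, ")",
           call. = FALSE)
    for (r in producing) {
      for (pre in emuPrecursors(net, emu, r)) {
        entries <- rbind(entries, data.frame(
          row = .termString(pre$factors), col = emu, flux = r$id,
          coeff = pre$coeff, stringsAsFactors = FALSE))
        for (f in pre$factors) {
          fm <- parseEMU(f)$met
          if (!(fm %in% bnd$substrates) && !(f %in% visited))
            queue <- c(queue, f)
        }
      }
    }
  }
  entries <- .aggregateEntries(entries)
  sizes <- sort(unique(vapply(visited, function(v) parseEMU(v)$size, 0L)))
  eams <- list()
  for (s in sizes) {
    cols <- visited[vapply(visited, function(v) parseEMU(v)$size == s, TRUE)]
    sub <- entries[entries$col %in% cols, , drop = FALSE]
    rownames(sub) <- NULL
    eams[[as.character(s)]] <- .buildEAM(s, cols, sub)
  }
  dec <- new("EMUDecomposition", eams = eams, targets = targets,
             network = net,
             equivalents = setNames(character(0), character(0)),
             reduced = FALSE, combined = FALSE)
  for (e in dec@eams) validObject(e)
  dec
}

# EMUs that must survive reduction: simulation targets plus every factor
# of every convolution term (their MDVs feed larger sizes).
.protectedEMUs <- function(dec) {
  prot <- dec@targets
  for (e in dec@eams) {
    conv <- e@entries$row[grepl("*", e@entries$row, fixed = TRUE)]
    prot <- c(prot, unlist(lapply(unique(conv), .termFactors)))
  }
  unique(prot)
}

#' Lump unimolecular EMU reaction chains
#'
#' In steady-state labeling only convolution (condensation) changes a
#' labeling pattern, so an EMU whose entire influx arrives through a
#' single reaction carries the coefficient-weighted mixture of its
#' sources' MDVs and can be eliminated: its column is deleted and its row
#' occurrences are replaced by its precursor term(s). This repeats until
#' no such column remains, then duplicate rows are merged by summing
#' coefficients. Target EMUs and convolution factors are never eliminated.
#'
#' Without symmetric metabolites a single-reaction column is exactly the
#' "solo element" column of the adjacency-matrix formulation; orientation
#' averaging of symmetric molecules can split that single reaction over
#' two cells, which are lumped together.
#'
#' @param dec an [EMUDecomposition]
#' @return the reduced [EMUDecomposition]
#' @examples
#' dec <- decomposeEMU(loadFixture("tca"), "Glu_12345")
#' countVariables(reduceUnimolecular(dec))
#' @export
reduceUnimolecular <- function(dec) {
  prot <- .protectedEMUs(dec)
  for (s in names(dec@eams)) {
    eam <- dec@eams[[s]]
    entries <- eam@entries
    cols <- eam@columns
    repeat {
      victim <- NULL
      for (c in cols) {
        if (c %in% prot) next
        ec <- entries[entries$col == c, , drop = FALSE]
        if (length(unique(ec$flux)) != 1L) next
        if (any(ec$row == c)) next
        victim <- c
        break
      }
      if (is.null(victim)) break
      ec <- entries[entries$col == victim, , drop = FALSE]
      w <- ec$coeff / sum(ec$coeff)
      entries <- entries[entries$col != victim, , drop = FALSE]
      cols <- setdiff(cols, victim)
      hit <- entries$row == victim
      if (any(hit)) {
        repl <- do.call(rbind, lapply(which(hit), function(i) {
          data.frame(row = ec$row, col = entries$col[i],
                     flux = entries$flux[i],
                     coeff = entries$coeff[i] * w,
                     stringsAsFactors = FALSE)
        }))
        entries <- rbind(entries[!hit, , drop = FALSE], repl)
      }
      entries <- .aggregateEntries(entries)
    }
    rownames(entries) <- NULL
    dec@eams[[s]] <- .buildEAM(eam@size, cols, entries)
  }
  dec@eams <- Filter(function(e) length(e@columns) > 0, dec@eams)
  dec@reduced <- TRUE
  for (e in dec@eams) validObject(e)
  dec
}

# Representative (lexicographically smallest name) of an EMU's
# rotational-equivalence class.
.symRep <- function(net, name) {
  e <- parseEMU(name)
  perm <- net@metabolites[[e$met]]$sym
  if (is.null(perm)) return(name)
  alt <- emuName(e$met, perm[e$atoms])
  min(name, alt)
}

.canonTerm <- function(net, term) {
  .termString(vapply(.termFactors(term), function(f) .symRep(net, f), ""))
}

#' Combine rotationally equivalent EMUs
#'
#' EMUs whose atom sets map onto each other under a metabolite's declared
#' rotational symmetry are indistinguishable and carry identical MDVs.
#' Each equivalence class is merged into its lexicographically smallest
#' member: row coefficients are summed; column coefficients are summed and
#' divided by the class cardinality.
#'
#' @param dec an [EMUDecomposition] (typically reduced first)
#' @return the combined [EMUDecomposition]; slot `equivalents` maps every
#'   renamed EMU to its representative.
#' @export
combineEquivalents <- function(dec) {
  net <- dec@network
  equiv <- character()
  for (s in names(dec@eams)) {
    eam <- dec@eams[[s]]
    entries <- eam@entries
    reps <- vapply(eam@columns, function(c) .symRep(net, c), "")
    for (i in seq_along(reps))
      if (reps[i] != eam@columns[i]) equiv[eam@columns[i]] <- reps[i]
    card <- table(reps)
    if (nrow(entries)) {
      entries$coeff <- entries$coeff / as.numeric(card[reps[match(
        entries$col, eam@columns)]])
      entries$col <- reps[match(entries$col, eam@columns)]
      entries$row <- vapply(entries$row, function(r) .canonTerm(net, r), "")
      entries <- .aggregateEntries(entries)
    }
    cols <- unique(reps)
    rownames(entries) <- NULL
    dec@eams[[s]] <- .buildEAM(eam@size, cols, entries)
  }
  # resolve renamed factors inside convolution rows of other sizes too
  dec@equivalents <- equiv
  dec@combined <- TRUE
  for (e in dec@eams) validObject(e)
  dec
}

#' Count EMU variables of a decomposition
#'
#' Number of unknown EMU variables summed over all sizes. Substrate EMUs
#' and convolution terms are known sources and are not counted; EMUs that
#' are rotationally equivalent are one variable (they necessarily carry
#' the same MDV), so an uncombined decomposition that still lists both
#' orientations of a symmetric molecule counts each class once.
#'
#' @param dec an [EMUDecomposition]
#' @return integer count
#' @examples
#' dec <- decomposeEMU(loadFixture("tca"), "Glu_12345")
#' countVariables(dec)                                        # 24
#' countVariables(combineEquivalents(reduceUnimolecular(dec))) # 9
#' @export
countVariables <- function(dec) {
  net <- dec@network
  total <- 0L
  for (e in dec@eams)
    total <- total + length(unique(vapply(e@columns, function(c)
      .symRep(net, c), "")))
  total
}

#' Per-size variable counts of a decomposition
#' @param dec an [EMUDecomposition]
#' @return named integer vector, one entry per EMU size
#' @export
countVariablesBySize <- function(dec) {
  net <- dec@network
  vapply(dec@eams, function(e)
    length(unique(vapply(e@columns, function(c) .symRep(net, c), ""))), 0L)
}

#' Export EAMs as a JSON report
#' @param dec an [EMUDecomposition]
#' @param path output path; if `NULL` the JSON string is returned
#' @export
exportEAMs <- function(dec, path = NULL) {
  rep <- lapply(dec@eams, function(e) {
    list(size = e@size, columns = e@columns, knowns = e@knowns,
         cells = lapply(seq_len(nrow(e@entries)), function(i)
           list(row = e@entries$row[i], col = e@entries$col[i],
                flux = e@entries$flux[i], coeff = e@entries$coeff[i])))
  })
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
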