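# Model dialect, one reaction per line:
#   id: M1 (atoms) [+ M2 (atoms) ...] ->  P1 (atoms) [+ ...]
#   id: M1 (atoms) <-> P1 (atoms)          (reversible; split into id f/b)
#   symmetric: Met 1-4,2-3                  (rotational symmetry axis)
# Comment lines start with '#'. Carbon counts are inferred from atom-map
# lengths and must be consistent across the file.

.parseTerm <- function(txt, rid) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([A-Za-z][A-Za-z0-9]*)\\s*\\(([a-z]*)\\)$",
                               txt))[[1]]
  if (length(m) != 3)
    stop("format error in reaction ", rid, ": cannot parse term '",
         trimws(txt), "'", call. = FALSE)
  list(met = m[2], atoms = m[3])
}

.parseSide <- function(txt, rid) {
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  lapply(parts, .parseTerm, rid = rid)
}

.mirror <- function(r, id) {
  list(id = id, base = r$base, dir = "b", reversible = TRUE,
       reactants = r$products, products = r$reactants)
}

#' Parse an atom-transition metabolic model
#'
#' Reads the plain-text model dialect (see Details) into a
#' [MetabolicNetwork]. Reversible reactions (`<->`) are split into a
#' forward/backward pair `idf`/`idb` with mirrored atom maps. Symmetry
#' declarations (`symmetric: Met 1-4,2-3`) attach a self-inverse atom
#' permutation to the named metabolite.
#'
#' @details Each reaction line is
#'   `id: M1 (atoms) [+ M2 (atoms)] -> P1 (atoms) [+ P2 (atoms)]`,
#'   where the atom string assigns one lowercase letter per carbon,
#'   position k being carbon k (1-based). A letter may appear at most once
#'   per side; every product letter must be sourced from a reactant letter
#'   (carbon balance), while reactant letters may go unused (carbon lost
#'   to species outside the model).
#'
#' @param text model file content (single string or character vector of lines).
#' @return a [MetabolicNetwork]
#' @examples
#' net <- parseModel(c("v1: A (ab) -> B (ab)", "v2: B (ab) <-> C (ba)"))
#' net
#' @seealso [readModel()], [serializeModel()], [loadFixture()]
#' @export
parseModel <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  mets <- list()
  reactions <- list()
  seen_ids <- character()
  sym_lines <- list()

  note_met <- function(term, rid) {
    n <- nchar(term$atoms)
    if (is.null(mets[[term$met]])) {
      mets[[term$met]] <<- list(name = term$met, n = n, sym = NULL)
    } else if (mets[[term$met]]$n != n) {
      stop("format error in reaction ", rid, ": atom string for ",
           term$met, " has length ", n, ", expected ", mets[[term$met]]$n,
           call. = FALSE)
    }
  }

  for (ln in lines) {
    if (grepl("^symmetric\\s*:", ln)) {
      m <- regmatches(ln, regexec(
        "^symmetric\\s*:\\s*([A-Za-z][A-Za-z0-9]*)\\s+(.+)$", ln))[[1]]
      if (length(m) != 3)
        stop("format error: cannot parse symmetry line '", ln, "'",
             call. = FALSE)
      sym_lines[[length(sym_lines) + 1L]] <- list(met = m[2], spec = m[3])
      next
    }
    m <- regmatches(ln, regexec("^(\\w+)\\s*:\\s*(.*)$", ln))[[1]]
    arrow <- if (grepl("<->", ln, fixed = TRUE)) "<->" else "->"
    sides <- if (length(m) == 3) strsplit(m[3], arrow, fixed = TRUE)[[1]]
    if (length(m) != 3 || length(sides) != 2)
      stop("format error: cannot parse line '", ln, "'", call. = FALSE)
    id <- m[2]; lhs <- trimws(sides[1]); rhs <- trimws(sides[2])
    if (id %in% seen_ids)
      stop("format error: duplicate flux id '", id, "'", call. = FALSE)
    seen_ids <- c(seen_ids, id)
    reac <- .parseSide(lhs, id)
    prod <- .parseSide(rhs, id)
    for (t in c(reac, prod)) note_met(t, id)

    rl <- unlist(strsplit(vapply(reac, `[[`, "", "atoms"), ""))
    pl <- unlist(strsplit(vapply(prod, `[[`, "", "atoms"), ""))
    if (anyDuplicated(rl))
      stop("format error in reaction ", id, ": repeated reactant atom letter",
           call. = FALSE)
    if (anyDuplicated(pl))
      stop("format error in reaction ", id, ": repeated product atom letter",
           call. = FALSE)
    if (!all(pl %in% rl))
      stop("carbon-balance error in reaction ", id, ": product atom(s) '",
           paste(setdiff(pl, rl), collapse = ","), "' unsourced",
           call. = FALSE)

    if (arrow == "<->") {
      fwd <- list(id = paste0(id, "f"), base = id, dir = "f",
                  reversible = TRUE, reactants = reac, products = prod)
      reactions <- c(reactions, list(fwd), list(.mirror(fwd, paste0(id, "b"))))
    } else {
      reactions <- c(reactions,
                     list(list(id = id, base = id, dir = "",
                               reversible = FALSE,
                               reactants = reac, products = prod)))
    }
  }

  for (s in sym_lines) {
    if (is.null(mets[[s$met]]))
      stop("format error: symmetry declared for unknown metabolite '",
           s$met, "'", call. = FALSE)
    n <- mets[[s$met]]$n
    perm <- seq_len(n)
    for (pair in strsplit(s$spec, ",")[[1]]) {
      ab <- as.integer(strsplit(trimws(pair), "-")[[1]])
      if (length(ab) != 2 || anyNA(ab) || any(ab < 1) || any(ab > n))
        stop("format error: bad symmetry pair '", pair, "' for ", s$met,
             call. = FALSE)
      perm[ab[1]] <- ab[2]
      perm[ab[2]] <- ab[1]
    }
    mets[[s$met]]$sym <- perm
  }

  new("MetabolicNetwork", metabolites = mets, reactions = reactions)
}

#' Read a model file from disk
#' @param path model file path
#' @return a [MetabolicNetwork]
#' @export
readModel <- function(path) parseModel(readLines(path, warn = FALSE))

#' Serialize a network back to the model dialect
#'
#' Inverse of [parseModel()]: forward/backward pairs are merged back into
#' a single `<->` line, and symmetry permutations are emitted as
#' `symmetric:` lines. `parseModel(serializeModel(net))` reproduces `net`.
#'
#' @param net a [MetabolicNetwork]
#' @return character vector of model lines
#' @export
serializeModel <- function(net) {
  fmt_side <- function(terms)
    paste(vapply(terms, function(t) sprintf("%s (%s)", t$met, t$atoms), ""),
          collapse = " + ")
  out <- character()
  skip <- character()
  for (r in net@reactions) {
    if (r$id %in% skip) next
    if (isTRUE(r$reversible) && r$dir == "f") {
      out <- c(out, sprintf("%s: %s <-> %s", r$base, fmt_side(r$reactants),
                            fmt_side(r$products)))
      skip <- c(skip, paste0(r$base, "b"))
    } else {
      out <- c(out, sprintf("%s: %s -> %s", r$id, fmt_side(r$reactants),
                            fmt_side(r$products)))
    }
  }
  for (m in net@metabolites) {
    if (is.null(m$sym)) next
    pairs <- character()
    done <- integer()
    for (i in seq_len(m$n)) {
      j <- m$sym[i]
      if (j != i && !(i %in% done)) {
        pairs <- c(pairs, sprintf("%d-%d", i, j))
        done <- c(done, i, j)
      }
    }
    out <- c(out, sprintf("symmetric: %s %s", m$name,
                          paste(pairs, collapse = ",")))
  }
  out
}

#' Write a network to a model file
#' @param net a [MetabolicNetwork]
#' @param path output path
#' @export
writeModel <- function(net, path) writeLines(serializeModel(net), path)

#' Load a bundled fixture network
#'
#' Two networks ship with the package: `"tca"`, a simplified TCA cycle
#' (aspartate and acetyl-CoA in, glutamate and CO2 out, reversible
#' fumarate/oxaloacetate interconversion, rotationally symmetric fumarate
#' and succinate), and `"xylose"`, a synthetic transcription of
#' *Clostridium acetobutylicum* xylose catabolism (phosphoketolase split,
#' reversible non-oxidative pentose phosphate pathway, glycolysis to
#' pyruvate, and the fermentative acetate / ethanol / butyrate / butanol /
#' acetone branches).
#'
#' @param name `"tca"` or `"xylose"`
#' @return a [MetabolicNetwork]
#' @examples
#' tca <- loadFixture("tca")
#' boundaryMetabolites(buildMAM(tca))
#' @export
loadFixture <- function(name) {
  name <- match.arg(name, c("tca", "xylose"))
  path <- system.file("extdata", paste0(name, ".model"), package = "EMUnet",
                      mustWork = TRUE)
  readModel(path)
}

#' Build the metabolite adjacency matrix
#'
#' Square matrix over all metabolites; cell (r, c) lists the reactions in
#' which r is a reactant and c a product. A reaction with r reactants and
#' p products contributes r*p cells.
#'
#' @param net a [MetabolicNetwork]
#' @return a [MAM]
#' @export
buildMAM <- function(net) {
  idx <- names(net@metabolites)
  if (is.null(idx)) idx <- character(0)
  n <- length(idx)
  cells <- matrix(vector("list", n * n), n, n, dimnames = list(idx, idx))
  for (r in net@reactions) {
    for (rt in r$reactants) for (pt in r$products) {
      cells[[rt$met, pt$met]] <- union(cells[[rt$met, pt$met]], r$id)
    }
  }
  new("MAM", index = idx, cells = cells)
}

#' Classify boundary metabolites of a MAM
#'
#' Substrates are metabolites whose MAM column is empty (no reaction
#' produces them); final products are those whose row is empty (no
#' reaction consumes them).
#'
#' @param mam a [MAM]
#' @return list with character vectors `substrates` and `products`
#' @export
boundaryMetabolites <- function(mam) {
  nz <- matrix(lengths(mam@cells) > 0, nrow = length(mam@index))
  list(substrates = mam@index[colSums(nz) == 0],
       products = mam@index[rowSums(nz) == 0])
}

#' Export a MAM as a JSON adjacency listing
#' @param mam a [MAM]
#' @param path output path; if `NULL`, the JSON string is returned
#' @return path (invisibly) or JSON string
#' @export
exportMAM <- function(mam, path = NULL) {
  adj <- list()
  for (r in mam@index) {
    row <- list()
    for (c in mam@index) {
      ids <- mam@cells[[r, c]]
      if (length(ids)) row[[c]] <- sort(ids)
    }
    if (length(row)) adj[[r]] <- row
  }
  json <- jsonlite::toJSON(adj, auto_unbox = FALSE, pretty = TRUE)
  if (is.null(json)) stop("serialization failed")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
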