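# GROMACS-dialect topology subset: [ defaults ], [ atomtypes ],
# [ moleculetype ] + [ atoms ], [ molecules ] are parsed; everything else is
# preserved verbatim and re-emitted in place. Units follow GROMACS: sigma nm,
# epsilon kJ/mol, charge e, mass amu.

.sectionRe <- "^[[:space:]]*\\[[[:space:]]*([A-Za-z0-9_-]+)[[:space:]]*\\]"

# sections that belong to the enclosing [ moleculetype ] block
.molScopedSections <- c("bonds", "pairs", "angles", "dihedrals", "exclusions",
                        "settles", "constraints", "position_restraints",
                        "virtual_sites2", "virtual_sites3", "virtual_sites4")

.stripComment <- function(line) sub(";.*$", "", line)

# drop trailing all-blank lines from a verbatim block
.trimBlock <- function(lines) {
  while (length(lines) && grepl("^[[:space:]]*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}

.isBlank <- function(line) grepl("^[[:space:]]*$", .stripComment(line))

.numField <- function(tok, what, lineno) {
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v))
    stop(sprintf("malformed numeric %s '%s' at line %d", what, tok, lineno),
         call. = FALSE)
  v
}

#' Read a force-field topology
#'
#' Parses the supported GROMACS-dialect subset into a [FFTopology-class].
#' Molecule roles (used to select scaling targets) are taken from a
#' `; role: solvent-ion` comment inside the `[ moleculetype ]` block, or from
#' the `roles` argument, which wins; unlisted molecules default to `"other"`.
#'
#' @param text topology text: a single string, a character vector of lines,
#'   or a file path (when `file = TRUE`).
#' @param roles optional named character vector, molecule name -> role
#'   (`"solvent-ion"`, `"solute"`, `"other"`).
#' @param file interpret `text` as a path.
#' @return a [FFTopology-class].
#' @examples
#' top <- readTopology(toyTopologyText())
#' netCharge(top, "CAT")
#' @export
readTopology <- function(text, roles = NULL, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  hdr <- regmatches(text, regexec(.sectionRe, text))
  secName <- vapply(hdr, function(h) if (length(h)) tolower(h[2]) else NA_character_,
                    character(1))
  hdrIdx <- which(!is.na(secName))
  if (!length(hdrIdx)) stop("no topology sections found", call. = FALSE)

  atomTypes <- data.frame(type = character(), atnum = character(),
                          mass = numeric(), charge = numeric(),
                          ptype = character(), sigma = numeric(),
                          epsilon = numeric(), stringsAsFactors = FALSE)
  molecules <- list()
  molCounts <- data.frame(name = character(), count = integer(),
                          stringsAsFactors = FALSE)
  defaultsRaw <- character()
  combRule <- NA_integer_
  passthrough <- list()
  layout <- character()
  preamble <- character()

  if (hdrIdx[1] > 1L) {
    preamble <- .trimBlock(text[seq_len(hdrIdx[1] - 1L)])
    if (!all(vapply(preamble, .isBlank, logical(1)))) layout <- "preamble"
    else preamble <- character()
  }

  currentMol <- NULL
  flushMol <- function() {
    if (!is.null(currentMol)) {
      m <- new("MoleculeDef", name = currentMol$name, nrexcl = currentMol$nrexcl,
               role = currentMol$role,
               atoms = currentMol$atoms %||% data.frame(
                 nr = integer(), type = character(), resnr = integer(),
                 residue = character(), atom = character(), cgnr = integer(),
                 charge = numeric(), mass = numeric(), stringsAsFactors = FALSE),
               extra = currentMol$extra)
      molecules[[m@name]] <<- m
      layout <<- c(layout, paste0("molecule:", m@name))
      currentMol <<- NULL
    }
  }

  nPass <- 0L
  for (k in seq_along(hdrIdx)) {
    i0 <- hdrIdx[k]
    i1 <- if (k < length(hdrIdx)) hdrIdx[k + 1L] - 1L else length(text)
    body <- if (i1 >= i0 + 1L) text[(i0 + 1L):i1] else character()
    lnos <- if (i1 >= i0 + 1L) (i0 + 1L):i1 else integer()
    sec <- secName[i0]
    dataRows <- which(!vapply(body, .isBlank, logical(1)))

    if (sec == "defaults") {
      flushMol()
      defaultsRaw <- .trimBlock(body)
      if (length(dataRows)) {
        toks <- strsplit(trimws(.stripComment(body[dataRows[1]])), "[[:space:]]+")[[1]]
        if (length(toks) >= 2L) combRule <- as.integer(toks[2])
      }
      layout <- c(layout, "defaults")

    } else if (sec == "atomtypes") {
      flushMol()
      for (r in dataRows) {
        toks <- strsplit(trimws(.stripComment(body[r])), "[[:space:]]+")[[1]]
        ln <- lnos[r]
        if (length(toks) == 6L) toks <- c(toks[1], NA_character_, toks[2:6])
        if (length(toks) != 7L)
          stop(sprintf("unsupported [ atomtypes ] record at line %d (need 6 or 7 fields)", ln),
               call. = FALSE)
        atomTypes <- rbind(atomTypes, data.frame(
          type = toks[1], atnum = toks[2],
          mass = .numField(toks[3], "mass", ln),
          charge = .numField(toks[4], "charge", ln),
          ptype = toks[5],
          sigma = .numField(toks[6], "sigma", ln),
          epsilon = .numField(toks[7], "epsilon", ln),
          stringsAsFactors = FALSE))
      }
      layout <- c(layout, "atomtypes")

    } else if (sec == "moleculetype") {
      flushMol()
      if (!length(dataRows))
        stop(sprintf("[ moleculetype ] at line %d has no name record", i0),
             call. = FALSE)
      toks <- strsplit(trimws(.stripComment(body[dataRows[1]])), "[[:space:]]+")[[1]]
      role <- "other"
      roleLine <- grep(";[[:space:]]*role[[:space:]]*[:=]", body, value = TRUE)
      if (length(roleLine))
        role <- trimws(sub(".*role[[:space:]]*[:=][[:space:]]*", "", roleLine[1]))
      currentMol <- list(name = toks[1],
                         nrexcl = if (length(toks) >= 2L) toks[2] else "3",
                         role = role, atoms = NULL, extra = character())

    } else if (sec == "atoms") {
      if (is.null(currentMol))
        stop(sprintf("[ atoms ] at line %d outside a moleculetype", i0),
             call. = FALSE)
      rows <- lapply(dataRows, function(r) {
        toks <- strsplit(trimws(.stripComment(body[r])), "[[:space:]]+")[[1]]
        ln <- lnos[r]
        if (!length(toks) %in% c(7L, 8L))
          stop(sprintf("unsupported [ atoms ] record at line %d (need 7 or 8 fields)", ln),
               call. = FALSE)
        data.frame(nr = as.integer(.numField(toks[1], "index", ln)),
                   type = toks[2],
                   resnr = as.integer(.numField(toks[3], "resnr", ln)),
                   residue = toks[4], atom = toks[5],
                   cgnr = as.integer(.numField(toks[6], "cgnr", ln)),
                   charge = .numField(toks[7], "charge", ln),
                   mass = if (length(toks) == 8L)
                     .numField(toks[8], "mass", ln) else NA_real_,
                   stringsAsFactors = FALSE)
      })
      currentMol$atoms <- do.call(rbind, rows)

    } else if (sec == "molecules") {
      flushMol()
      for (r in dataRows) {
        toks <- strsplit(trimws(.stripComment(body[r])), "[[:space:]]+")[[1]]
        molCounts <- rbind(molCounts, data.frame(
          name = toks[1],
          count = as.integer(.numField(toks[2], "count", lnos[r])),
          stringsAsFactors = FALSE))
      }
      layout <- c(layout, "molcounts")

    } else if (!is.null(currentMol) && sec %in% .molScopedSections) {
      # bonded section inside a molecule: keep verbatim with the molecule
      currentMol$extra <- c(currentMol$extra, .trimBlock(text[i0:i1]))

    } else {
      flushMol()
      nPass <- nPass + 1L
      id <- as.character(nPass)
      passthrough[[id]] <- .trimBlock(text[i0:i1])
      layout <- c(layout, paste0("passthrough:", id))
    }
  }
  flushMol()

  # fill missing per-atom masses from the atom-type table
  for (nm in names(molecules)) {
    a <- molecules[[nm]]@atoms
    miss <- is.na(a$mass)
    if (any(miss)) {
      idx <- match(a$type[miss], atomTypes$type)
      if (anyNA(idx)) {
        bad <- unique(a$type[miss][is.na(idx)])
        stop(sprintf("atom(s) %s in molecule '%s' reference undefined atom type '%s'",
                     paste(a$atom[miss][is.na(idx)], collapse = ", "), nm, bad[1]),
             call. = FALSE)
      }
      a$mass[miss] <- atomTypes$mass[idx]
      molecules[[nm]]@atoms <- a
    }
    bad <- setdiff(unique(a$type), atomTypes$type)
    if (length(bad))
      stop(sprintf("atom '%s' in molecule '%s' references undefined atom type '%s'",
                   a$atom[match(bad[1], a$type)], nm, bad[1]), call. = FALSE)
  }

  if (!is.null(roles)) {
    for (nm in names(roles)) {
      if (!nm %in% names(molecules))
        stop(sprintf("roles names unknown molecule '%s'", nm), call. = FALSE)
      molecules[[nm]]@role <- unname(roles[nm])
      validObject(molecules[[nm]])
    }
  }

  new("FFTopology", atomTypes = atomTypes, molecules = molecules,
      molCounts = molCounts, defaultsRaw = defaultsRaw,
      combinationRule = combRule, passthrough = passthrough,
      preamble = preamble, layout = layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a force-field topology
#'
#' Emits canonical fixed-width formatting for the parsed sections (charges
#' with 8 decimal places so that net charges survive the round-trip to better
#' than 1e-6 e) and re-emits passthrough blocks verbatim in their original
#' positions. A post-write check warns if any molecule's net charge read back
#' from the emitted text drifts by more than 1e-6 e.
#'
#' @param top a [FFTopology-class].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path = NULL`) the character vector of
#'   emitted lines.
#' @export
writeTopology <- function(top, path = NULL) {
  stopifnot(is(top, "FFTopology"))
  out <- character()
  add <- function(...) out <<- c(out, ...)

  for (tok in top@layout) {
    if (tok == "preamble") {
      add(top@preamble)
    } else if (tok == "defaults") {
      add("[ defaults ]", top@defaultsRaw, "")
    } else if (tok == "atomtypes") {
      add("[ atomtypes ]",
          "; type    at.num      mass    charge  ptype        sigma      epsilon")
      at <- top@atomTypes
      for (i in seq_len(nrow(at)))
        add(sprintf("%-8s %7s %9.4f %9.4f %6s %14.8e %14.8e",
                    at$type[i], ifelse(is.na(at$atnum[i]), "", at$atnum[i]),
                    at$mass[i], at$charge[i], at$ptype[i],
                    at$sigma[i], at$epsilon[i]))
      add("")
    } else if (startsWith(tok, "molecule:")) {
      m <- top@molecules[[sub("^molecule:", "", tok)]]
      add("[ moleculetype ]", "; name  nrexcl",
          sprintf("%-8s %s", m@name, m@nrexcl),
          sprintf("; role: %s", m@role), "", "[ atoms ]",
          ";  nr  type  resnr residue atom cgnr        charge       mass")
      a <- m@atoms
      for (i in seq_len(nrow(a)))
        add(sprintf("%5d %-6s %5d %-6s %-5s %4d %14.8f %10.5f",
                    a$nr[i], a$type[i], a$resnr[i], a$residue[i],
                    a$atom[i], a$cgnr[i], a$charge[i], a$mass[i]))
      add("")
      if (length(m@extra)) add(m@extra, "")
    } else if (tok == "molcounts") {
      add("[ molecules ]")
      for (i in seq_len(nrow(top@molCounts)))
        add(sprintf("%-8s %6d", top@molCounts$name[i], top@molCounts$count[i]))
      add("")
    } else if (startsWith(tok, "passthrough:")) {
      add(top@passthrough[[sub("^passthrough:", "", tok)]], "")
    }
  }

  reread <- readTopology(out)
  for (nm in names(top@molecules)) {
    drift <- abs(sum(top@molecules[[nm]]@atoms$charge) -
                 sum(reread@molecules[[nm]]@atoms$charge))
    if (drift > 1e-6)
      warning(sprintf("net charge of '%s' drifted by %.2e e on write", nm, drift))
  }

  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Minimal example topology text
#'
#' A small two-molecule (monatomic cation/anion pair plus a neutral two-site
#' solute) topology in the supported dialect, used in examples and tests.
#'
#' @return character vector of topology lines.
#' @export
toyTopologyText <- function() {
  c("; toy ionic-liquid topology",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    "1    2    yes    0.5    0.8333",
    "",
    "[ atomtypes ]",
    "; type at.num mass    charge ptype sigma   epsilon",
    "CA   7   100.000  0.0000  A  0.35000000  0.65000000",
    "AN   9   140.000  0.0000  A  0.40000000  0.50000000",
    "SO   6    60.000  0.0000  A  0.33000000  0.40000000",
    "",
    "[ moleculetype ]",
    "CAT  3",
    "; role: solvent-ion",
    "[ atoms ]",
    "1  CA  1  CAT  C1  1   1.00000000  100.000",
    "",
    "[ moleculetype ]",
    "ANI  3",
    "; role: solvent-ion",
    "[ atoms ]",
    "1  AN  1  ANI  N1  1  -1.00000000  140.000",
    "",
    "[ moleculetype ]",
    "SOL  3",
    "; role: solute",
    "[ atoms ]",
    "1  SO  1  SOL  S1  1   0.25000000   60.000",
    "2  SO  1  SOL  S2  1  -0.25000000   60.000",
    "[ bonds ]",
    "; preserved verbatim",
    "1 2 1 0.15 1000.0",
    "",
    "[ system ]",
    "toy cell",
    "",
    "[ molecules ]",
    "CAT  16",
    "ANI  16",
    "SOL  1")
}
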