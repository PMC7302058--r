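# NEXUS input/output for standard (categorical) character matrices with
# CHARSET support, plus the dataset-curation operations: overlap screening,
# the missing-data taxon filter and removal of parsimony-uninformative
# characters.

.tokenizeCells <- function(str, line) {
  # split a row of a NEXUS matrix into per-character tokens, honouring
  # {..} and (..) polymorphism groups
  chars <- strsplit(str, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars))
        stop(sprintf("line %d: unterminated polymorphism group", line))
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

.stripNexusComments <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # non-greedy removal of [...] comments (no nesting support needed for
  # the standard files handled here)
  txt <- gsub("\\[[^]]*\\]", "", txt)
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

#' Construct a character matrix from state tokens
#'
#' Builds a \linkS4class{CharacterMatrix} from a taxa-by-characters matrix of
#' token strings using the same cell notation as a NEXUS file: a single
#' symbol for a fixed score, \code{"?"} for missing, \code{"-"} for
#' inapplicable, and \code{"{..}"} or \code{"(..)"} for a polymorphic or
#' uncertain state set (the two notations are treated identically).
#'
#' @param tokens character matrix (rows = taxa, with rownames) of cell
#'   tokens, e.g. \code{"0"}, \code{"?"}, \code{"{01}"}.
#' @param symbols character vector of state symbols in code order
#'   (symbol i encodes state i-1).
#' @param missing,gap tokens denoting missing and inapplicable cells.
#' @param charsets named list of integer character-index vectors.
#' @return a \linkS4class{CharacterMatrix}.
#' @examples
#' tok <- rbind(A = c("0", "0"), B = c("0", "1"),
#'              C = c("1", "{01}"), D = c("1", "?"))
#' characterMatrix(tok)
#' @export
characterMatrix <- function(tokens, symbols = as.character(0:9),
                            missing = "?", gap = "-", charsets = list()) {
  tokens <- as.matrix(tokens)
  if (is.null(rownames(tokens))) stop("taxon labels (rownames) required")
  nt <- nrow(tokens); nc <- ncol(tokens)
  masks <- matrix(0L, nt, nc)
  special <- matrix(0L, nt, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nt)) {
      tok <- tokens[i, j]
      if (tok == missing) { special[i, j] <- 1L; next }
      if (tok == gap) { special[i, j] <- 2L; next }
      syms <- if (nchar(tok) > 1L)
        strsplit(gsub("[{}() ,]", "", tok), "")[[1]] else tok
      codes <- match(syms, symbols) - 1L
      if (anyNA(codes))
        stop(sprintf("unknown state symbol '%s' (taxon %s, character %d)",
                     tok, rownames(tokens)[i], j))
      masks[i, j] <- sum(bitwShiftL(1L, unique(codes)))
    }
  }
  alphabet <- pmax(1L, apply(masks, 2, function(col) {
    if (all(col == 0L)) return(1L)
    as.integer(floor(log2(max(col))) + 1L)
  }))
  rownames(masks) <- rownames(special) <- rownames(tokens)
  colnames(masks) <- colnames(special) <-
    if (is.null(colnames(tokens))) sprintf("c%d", seq_len(nc)) else colnames(tokens)
  new("CharacterMatrix", masks = masks, special = special,
      alphabet = as.integer(alphabet), charsets = charsets)
}

#' Read a NEXUS character matrix
#'
#' Parses a NEXUS file with a DATA or CHARACTERS block (standard datatype)
#' and an optional SETS block. Cell decoding keeps the distinction between
#' missing (\code{?}) and inapplicable (\code{-}) scores and decodes both
#' \code{\{..\}} and \code{(..)} groups as state sets. CHARSET definitions
#' (index lists and ranges, 1-based) are loaded into the matrix's charsets.
#'
#' @param path path to a NEXUS file.
#' @return a \linkS4class{CharacterMatrix}.
#' @seealso [writeNexus()] for the inverse; the two round-trip.
#' @export
readNexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- .stripNexusComments(readLines(path, warn = FALSE))
  up <- toupper(lines)
  if (!any(grepl("#NEXUS", up))) stop("not a NEXUS file (missing #NEXUS header)")
  # locate a DATA or CHARACTERS block
  beg <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(beg)) stop("no DATA or CHARACTERS block found")
  ends <- grep("^\\s*END\\s*;", up)
  endBlk <- ends[ends > beg[1]][1]
  if (is.na(endBlk)) stop(sprintf("line %d: unterminated block", beg[1]))
  blk <- lines[(beg[1] + 1L):(endBlk - 1L)]
  blkUp <- toupper(blk)
  offset <- beg[1]

  getOpt <- function(text, key, default = NULL) {
    m <- regmatches(text, regexpr(paste0(key, "\\s*=\\s*(\"[^\"]*\"|\\S+)"),
                                  text, ignore.case = TRUE))
    if (!length(m)) return(default)
    val <- sub(paste0("(?i)", key, "\\s*=\\s*"), "", m[1], perl = TRUE)
    gsub("[\";]", "", val)
  }
  joined <- paste(blk, collapse = " ")
  ntax <- as.integer(getOpt(joined, "NTAX"))
  nchar_ <- as.integer(getOpt(joined, "NCHAR"))
  if (is.na(ntax) || is.na(nchar_))
    stop("DIMENSIONS with NTAX and NCHAR required")
  symRaw <- getOpt(joined, "SYMBOLS", "0123456789")
  symbols <- strsplit(gsub("\\s", "", symRaw), "")[[1]]
  missTok <- getOpt(joined, "MISSING", "?")
  gapTok <- getOpt(joined, "GAP", "-")

  mstart <- grep("^\\s*MATRIX\\s*$|^\\s*MATRIX\\b", blkUp)
  if (!length(mstart)) stop("MATRIX command not found")
  rows <- list()
  i <- mstart[1] + 1L
  while (i <= length(blk)) {
    ln <- trimws(blk[i])
    if (ln == ";" || grepl(";\\s*$", ln)) {
      ln <- sub(";\\s*$", "", ln)
      if (nzchar(trimws(ln))) rows[[length(rows) + 1L]] <- c(trimws(ln), offset + i)
      break
    }
    if (nzchar(ln)) rows[[length(rows) + 1L]] <- c(ln, offset + i)
    i <- i + 1L
  }
  if (length(rows) != ntax)
    stop(sprintf("expected %d taxon rows in MATRIX, found %d", ntax, length(rows)))
  labs <- character(ntax)
  tokens <- matrix("", ntax, nchar_)
  for (r in seq_len(ntax)) {
    ln <- rows[[r]][1]
    lineNo <- as.integer(rows[[r]][2])
    if (startsWith(ln, "'")) {
      close <- regexpr("'", substring(ln, 2)) + 1L
      labs[r] <- substring(ln, 2, close - 1L)
      rest <- substring(ln, close + 1L)
    } else {
      sp <- regexpr("\\s", ln)
      if (sp < 0) stop(sprintf("line %d: taxon label without cells", lineNo))
      labs[r] <- substring(ln, 1, sp - 1L)
      rest <- substring(ln, sp + 1L)
    }
    cells <- .tokenizeCells(rest, lineNo)
    if (length(cells) != nchar_)
      stop(sprintf("line %d: expected %d characters for taxon %s, found %d",
                   lineNo, nchar_, labs[r], length(cells)))
    tokens[r, ] <- cells
  }
  if (anyDuplicated(labs))
    stop("duplicate taxon label: ", labs[duplicated(labs)][1])
  rownames(tokens) <- labs

  # SETS block (optional)
  csets <- list()
  sbeg <- grep("^\\s*BEGIN\\s+SETS\\s*;", up)
  if (length(sbeg)) {
    send <- ends[ends > sbeg[1]][1]
    stext <- paste(lines[(sbeg[1] + 1L):(send - 1L)], collapse = " ")
    defs <- regmatches(stext,
      gregexpr("(?i)CHARSET\\s+\\S+\\s*=[^;]+;", stext, perl = TRUE))[[1]]
    for (d in defs) {
      nm <- sub("(?i)^CHARSET\\s+(\\S+)\\s*=.*$", "\\1", d, perl = TRUE)
      body <- sub("(?i)^CHARSET\\s+\\S+\\s*=\\s*", "", sub(";\\s*$", "", d), perl = TRUE)
      parts <- strsplit(trimws(body), "\\s+")[[1]]
      idx <- integer(0)
      for (p in parts) {
        if (grepl("^\\d+-\\d+$", p)) {
          ab <- as.integer(strsplit(p, "-")[[1]])
          idx <- c(idx, ab[1]:ab[2])
        } else if (grepl("^\\d+$", p)) {
          idx <- c(idx, as.integer(p))
        } else if (toupper(p) == "ALL") {
          idx <- c(idx, seq_len(nchar_))
        } else {
          stop("unsupported CHARSET entry: ", p)
        }
      }
      csets[[nm]] <- sort(unique(idx))
    }
  }
  characterMatrix(tokens, symbols = symbols, missing = missTok, gap = gapTok,
                  charsets = csets)
}

.cellTokens <- function(cm) {
  syms <- as.character(0:29)
  nt <- nTaxa(cm); nc <- nCharacters(cm)
  tok <- matrix("?", nt, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nt)) {
      if (cm@special[i, j] == 1L) { tok[i, j] <- "?"; next }
      if (cm@special[i, j] == 2L) { tok[i, j] <- "-"; next }
      states <- which(bitwAnd(cm@masks[i, j], bitwShiftL(1L, 0:29)) != 0L) - 1L
      tok[i, j] <- if (length(states) == 1L) syms[states + 1L] else
        paste0("{", paste(syms[states + 1L], collapse = ""), "}")
    }
  }
  rownames(tok) <- taxa(cm)
  tok
}

#' Write a NEXUS character matrix
#'
#' Emits a DATA block (standard datatype, \code{MISSING=?} \code{GAP=-},
#' polymorphism as \code{\{..\}}) and, when the matrix carries charsets,
#' a SETS block with one CHARSET per set. [readNexus()] on the output
#' reproduces the matrix exactly.
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNexus <- function(cm, path) {
  tok <- .cellTokens(cm)
  nstates <- max(cm@alphabet)
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nTaxa(cm), nCharacters(cm)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(0:(nstates - 1L), collapse = "")),
    "  MATRIX"
  )
  labs <- taxa(cm)
  quoted <- ifelse(grepl("[^A-Za-z0-9_.]", labs), paste0("'", labs, "'"), labs)
  pad <- max(nchar(quoted)) + 2L
  for (i in seq_len(nTaxa(cm))) {
    lines <- c(lines, sprintf("    %-*s%s", pad, quoted[i],
                              paste(tok[i, ], collapse = "")))
  }
  lines <- c(lines, "  ;", "END;")
  if (length(cm@charsets)) {
    lines <- c(lines, "BEGIN SETS;")
    for (nm in names(cm@charsets)) {
      idx <- sort(cm@charsets[[nm]])
      # compress runs into ranges
      runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      ent <- vapply(runs, function(r)
        if (length(r) > 1L) sprintf("%d-%d", r[1], r[length(r)])
        else as.character(r), "")
      lines <- c(lines, sprintf("  CHARSET %s = %s;", nm,
                                paste(ent, collapse = " ")))
    }
    lines <- c(lines, "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Define the craniodental/postcranial partition of a matrix
#'
#' Labels every character as craniodental, postcranial or other. Characters
#' outside both sets (e.g. integument, egg or ecology characters) are
#' labelled \code{other} and excluded from every incongruence test.
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param cranio,post charset name or integer index vector for each
#'   analysis partition; the two must be disjoint.
#' @return a \linkS4class{PartitionScheme}.
#' @export
buildPartitionScheme <- function(cm, cranio, post) {
  ci <- .resolveChars(cm, cranio)
  pi_ <- .resolveChars(cm, post)
  if (length(intersect(ci, pi_)))
    stop("craniodental and postcranial sets overlap")
  lab <- rep("other", nCharacters(cm))
  lab[ci] <- "craniodental"
  lab[pi_] <- "postcranial"
  new("PartitionScheme",
      labels = factor(lab, levels = c("craniodental", "postcranial", "other")))
}

#' Cell overlap between two matrices
#'
#' The number of (taxon, character) positions present in both matrices,
#' as a percentage of the cell count of the smaller matrix. Shared taxa are
#' matched by label; shared characters by exact id match unless an explicit
#' \code{charMap} is supplied. Overlap counts replicated positions
#' regardless of the scored states.
#'
#' @param m1,m2 \linkS4class{CharacterMatrix} objects.
#' @param charMap optional named character vector mapping character ids of
#'   \code{m1} to ids of \code{m2}.
#' @return overlap percentage in \code{[0, 100]}.
#' @export
matrixOverlap <- function(m1, m2, charMap = NULL) {
  sharedTaxa <- intersect(taxa(m1), taxa(m2))
  if (is.null(charMap)) {
    sharedChars <- length(intersect(characterIds(m1), characterIds(m2)))
  } else {
    sharedChars <- sum(names(charMap) %in% characterIds(m1) &
                       charMap %in% characterIds(m2))
  }
  smaller <- min(nTaxa(m1) * nCharacters(m1), nTaxa(m2) * nCharacters(m2))
  100 * length(sharedTaxa) * sharedChars / smaller
}

.variantFlags <- function(cm, chars = seq_len(nCharacters(cm))) {
  # at least two distinct fixed observed states
  vapply(chars, function(j) {
    col <- cm@masks[, j]
    obs <- col[cm@special[, j] == 0L]
    fixed <- obs[bitwAnd(obs, obs - 1L) == 0L]
    length(unique(fixed)) >= 2L
  }, logical(1))
}

.informativeFlags <- function(cm, chars = seq_len(nCharacters(cm))) {
  # parsimony-informative: at least two states, each observed (as a fixed
  # singleton score) in at least two taxa
  vapply(chars, function(j) {
    col <- cm@masks[, j]
    obs <- col[cm@special[, j] == 0L]
    fixed <- obs[bitwAnd(obs, obs - 1L) == 0L]  # single-bit masks
    if (!length(fixed)) return(FALSE)
    tab <- table(fixed)
    sum(tab >= 2L) >= 2L
  }, logical(1))
}

.subsetMatrix <- function(cm, taxaKeep = taxa(cm),
                          charKeep = seq_len(nCharacters(cm))) {
  rows <- match(taxaKeep, taxa(cm))
  masks <- cm@masks[rows, charKeep, drop = FALSE]
  special <- cm@special[rows, charKeep, drop = FALSE]
  newPos <- integer(nCharacters(cm))
  newPos[charKeep] <- seq_along(charKeep)
  csets <- lapply(cm@charsets, function(idx) {
    kept <- idx[idx %in% charKeep]
    sort(newPos[kept])
  })
  csets <- csets[lengths(csets) > 0L]
  new("CharacterMatrix", masks = masks, special = special,
      alphabet = cm@alphabet[charKeep], charsets = csets)
}

#' Remove parsimony-uninformative characters
#'
#' A character is parsimony-uninformative when fewer than two of its states
#' are each observed (as fixed scores) in two or more taxa; this includes
#' invariant and autapomorphic characters. Missing and inapplicable cells
#' are ignored.
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param mode \code{"all"} strips every uninformative character;
#'   \code{"newly"} strips only characters that were informative in
#'   \code{reference} but are uninformative in \code{cm} (the curation
#'   rule: characters rendered uninformative by taxon removal).
#' @param reference the pre-curation matrix, required for
#'   \code{mode = "newly"}.
#' @return the reduced \linkS4class{CharacterMatrix} (charsets remapped).
#' @export
removeUninformative <- function(cm, mode = c("all", "newly"),
                                reference = NULL) {
  mode <- match.arg(mode)
  inf <- .informativeFlags(cm)
  if (mode == "all") {
    keep <- which(inf)
  } else {
    if (is.null(reference)) stop("mode='newly' needs the reference matrix")
    refIds <- characterIds(reference)
    wasInf <- .informativeFlags(reference)[match(characterIds(cm), refIds)]
    keep <- which(inf | !wasInf)
  }
  .subsetMatrix(cm, charKeep = keep)
}

#' Curate a partitioned matrix
#'
#' One-pass curation: first remove every taxon whose missing plus
#' inapplicable fraction exceeds \code{threshold} within either the
#' craniodental or the postcranial partition; then remove the characters
#' rendered parsimony-uninformative or invariant by those taxon deletions.
#' An optional \code{iterate} flag repeats the pass to a fixpoint (off by
#' default; the single pass mirrors the stated curation order).
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param scheme a \linkS4class{PartitionScheme} covering \code{cm}.
#' @param threshold missing-data fraction above which a taxon is dropped.
#' @param iterate repeat until no further removals.
#' @return list with elements \code{matrix} (curated
#'   \linkS4class{CharacterMatrix}), \code{scheme} (labels of surviving
#'   characters) and \code{report} (a \linkS4class{CurationReport}).
#' @export
curateMatrix <- function(cm, scheme, threshold = 0.40, iterate = FALSE) {
  if (length(scheme@labels) != nCharacters(cm))
    stop("scheme does not cover the matrix")
  allRemovedTaxa <- data.frame(taxon = character(0), frac_cranio = numeric(0),
                               frac_post = numeric(0))
  allRemovedChars <- data.frame(index = integer(0), id = character(0),
                                reason = character(0))
  labels <- scheme@labels
  repeat {
    ci <- which(labels == "craniodental")
    pi_ <- which(labels == "postcranial")
    if (!length(ci) || !length(pi_))
      stop("both analysis partitions must retain at least one character")
    fc <- rowMeans(cm@special[, ci, drop = FALSE] != 0L)
    fp <- rowMeans(cm@special[, pi_, drop = FALSE] != 0L)
    bad <- fc > threshold | fp > threshold
    if (all(bad)) stop("curation removed every taxon: degenerate result")
    if (!any(bad)) break
    allRemovedTaxa <- rbind(allRemovedTaxa,
      data.frame(taxon = taxa(cm)[bad], frac_cranio = fc[bad],
                 frac_post = fp[bad]))
    before <- cm
    wasInf <- .informativeFlags(before)
    wasVar <- .variantFlags(before)
    cm <- .subsetMatrix(cm, taxaKeep = taxa(cm)[!bad])
    nowInf <- .informativeFlags(cm)
    nowVar <- .variantFlags(cm)
    newlyUninf <- wasInf & !nowInf
    newlyInvar <- wasVar & !nowVar
    dropChars <- which(newlyUninf | newlyInvar)
    if (length(dropChars)) {
      allRemovedChars <- rbind(allRemovedChars,
        data.frame(index = dropChars, id = characterIds(cm)[dropChars],
                   reason = ifelse(newlyInvar[dropChars],
                                   "rendered invariant by taxon removal",
                                   "rendered uninformative by taxon removal")))
      keep <- setdiff(seq_len(nCharacters(cm)), dropChars)
      cm <- .subsetMatrix(cm, charKeep = keep)
      labels <- factor(as.character(labels[keep]),
                       levels = c("craniodental", "postcranial", "other"))
    }
    if (!iterate) break
  }
  list(matrix = cm,
       scheme = new("PartitionScheme", labels = labels),
       report = new("CurationReport", removedTaxa = allRemovedTaxa,
                    removedCharacters = allRemovedChars,
                    threshold = threshold))
}

#' Missing-data fractions per partition
#'
#' Percentage of missing plus inapplicable cells within each partition and
#' in both partitions combined.
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param scheme a \linkS4class{PartitionScheme}.
#' @return named numeric vector: \code{cranio}, \code{post}, \code{total}.
#' @export
missingPercent <- function(cm, scheme) {
  ci <- which(scheme@labels == "craniodental")
  pi_ <- which(scheme@labels == "postcranial")
  both <- c(ci, pi_)
  c(cranio = 100 * mean(cm@special[, ci, drop = FALSE] != 0L),
    post = 100 * mean(cm@special[, pi_, drop = FALSE] != 0L),
    total = 100 * mean(cm@special[, both, drop = FALSE] != 0L))
}
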