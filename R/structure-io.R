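# PDB-format reading and writing. Parsing goes through bio3d; this layer
# resolves altlocs, maps selenomethionine, drops heteroatoms/waters and
# assembles the per-residue table the descriptor computations work on.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Read a PDB-format structure
#'
#' Parses PDB-format text into a [ProteinStructure-class]. One residue row
#' is kept per standard amino-acid residue with a complete N, CA, C
#' backbone; heteroatoms, waters and hydrogens are dropped; MSE is mapped
#' to methionine; other non-standard residues are skipped with a warning.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties: first in file order).
#'
#' @param pdbSource path to a PDB file, or a character vector of PDB-format
#'   lines (anything containing a newline or of length > 1 is treated as
#'   text).
#' @param chainFilter optional character vector of chain ids to keep.
#' @param pdbId identifier to store; defaults to the file stem or "struct".
#' @return a [ProteinStructure-class]; descriptor columns (side-chain
#'   centers, accessibility, torsion domains) are NA until computed.
#' @seealso [computeSidechainCenters()], [computeAccessibility()],
#'   [assignTorsionDomains()]
#' @export
readStructure <- function(pdbSource, chainFilter = NULL, pdbId = NULL) {
  isText <- length(pdbSource) > 1L || grepl("\n", pdbSource[1]) ||
    grepl("^(ATOM|HETATM|HEADER|REMARK|EXPDTA)", pdbSource[1])
  if (isText) {
    lines <- unlist(strsplit(pdbSource, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(pdbId)) pdbId <- "struct"
  } else {
    path <- pdbSource
    if (!file.exists(path)) stop("no such PDB file: ", path)
    lines <- readLines(path, warn = FALSE)
    if (is.null(pdbId)) pdbId <- sub("\\.pdb$", "", basename(path))
  }

  resolution <- NA_real_
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem)) {
    m <- regmatches(rem[1],
                    regexpr("(?<=RESOLUTION.)\\s*[0-9]+\\.?[0-9]*",
                            rem[1], perl = TRUE))
    if (length(m)) resolution <- as.numeric(m)
  }
  method <- NA_character_
  exp <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp)) method <- trimws(sub("^EXPDTA", "", exp[1]))

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e))
  )
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # selenomethionine comes in as HETATM; treat as MET
  isMse <- at$resid == "MSE"
  at$resid[isMse] <- "MET"
  at$elety[isMse & at$elety == "SE"] <- "SD"
  at <- at[at$type == "ATOM" | isMse, , drop = FALSE]
  if (!is.null(chainFilter)) at <- at[at$chain %in% chainFilter, , drop = FALSE]

  elem <- if ("elesy" %in% names(at)) toupper(at$elesy) else NA_character_
  guess <- toupper(substr(gsub("[0-9']", "", at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  at$elem <- elem
  at <- at[!(at$elem %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  known <- at$resid %in% AA3
  if (any(!known)) {
    warning("skipping non-standard residue(s): ",
            paste(unique(at$resid[!known]), collapse = ", "))
    at <- at[known, , drop = FALSE]
  }
  if (!nrow(at)) stop("no residues after filtering")

  # altloc: highest occupancy per (chain, resno, ins, atom name), tie first
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(factor(key, levels = unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
           drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, ins = at$insert,
    resid = at$resid, aa = AA1[match(at$resid, AA3)],
    elety = at$elety, elem = at$elem,
    sidechain = !(at$elety %in% .BACKBONE),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )

  rkey <- paste(atoms$chain, atoms$resno, atoms$ins)
  ures <- unique(rkey)
  rows <- lapply(ures, function(k) {
    a <- atoms[rkey == k, , drop = FALSE]
    pick <- function(name) {
      i <- match(name, a$elety)
      if (is.na(i)) rep(NA_real_, 3) else c(a$x[i], a$y[i], a$z[i])
    }
    n <- pick("N"); ca <- pick("CA"); cc <- pick("C")
    if (anyNA(c(n, ca, cc))) return(NULL)
    data.frame(
      chain = a$chain[1], resno = a$resno[1], ins = a$ins[1], aa = a$aa[1],
      Nx = n[1], Ny = n[2], Nz = n[3],
      CAx = ca[1], CAy = ca[2], CAz = ca[3],
      Cx = cc[1], Cy = cc[2], Cz = cc[3],
      scx = NA_real_, scy = NA_real_, scz = NA_real_,
      acc = NA_real_, phi = NA_real_, psi = NA_real_,
      tdom = NA_character_, stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped)
    warning(dropped, " residue(s) dropped for incomplete N/CA/C backbone")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no residues after filtering")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  new("ProteinStructure", pdbId = pdbId, atoms = atoms, residues = res,
      resolution = resolution, experimentalMethod = method)
}

#' Write a structure back to PDB format
#'
#' Emits standard ATOM records (coordinates to 3 decimals, PDB precision)
#' plus HEADER/EXPDTA/REMARK 2 metadata when known, so that
#' `readStructure(writeStructure(x))` round-trips residue identity,
#' ordering and coordinates.
#'
#' @param s a [ProteinStructure-class].
#' @param file output path, or NULL to return the lines invisibly only.
#' @return character vector of PDB lines, invisibly.
#' @export
writeStructure <- function(s, file = NULL) {
  a <- s@atoms
  hdr <- c(
    sprintf("HEADER    PROTEIN                                 01-JAN-00   %-4s",
            toupper(substr(s@pdbId, 1, 4))),
    if (!is.na(s@experimentalMethod))
      sprintf("EXPDTA    %s", s@experimentalMethod),
    if (!is.na(s@resolution))
      sprintf("REMARK   2 RESOLUTION. %5.2f ANGSTROMS.", s@resolution)
  )
  name <- ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety)
  rec <- sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
                 ifelse(a$ins == "", " ", a$ins),
                 a$x, a$y, a$z, 1, 0, a$elem)
  lines <- c(hdr, rec, "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
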