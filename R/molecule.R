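# SMILES -> annotated molecular graph, built on ChemmineR/ChemmineOB.
# Parsed molecules are cached per SMILES string: HTE tables repeat a small
# component vocabulary thousands of times.

.mol_cache <- new.env(parent = emptyenv())

# MDL V2000 old-style charge codes as stored by ChemmineR (atomblock col "C6")
.mdl_charge <- function(code) {
  out <- integer(length(code))
  out[code == 1] <- 3L
  out[code == 2] <- 2L
  out[code == 3] <- 1L
  out[code == 5] <- -1L
  out[code == 6] <- -2L
  out[code == 7] <- -3L
  out
}

.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into an annotated molecular graph
#'
#' Wraps \code{ChemmineR::smiles2sdf} and augments the resulting connection
#' table with aromaticity (ring perception), formal charges, implicit
#' hydrogen counts, degrees and a heuristic hybridization assignment.
#' Results are memoised per SMILES string.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements \code{elements} (character), \code{charge}
#'   (integer), \code{aromatic_atom} (logical), \code{n_h} (implicit
#'   hydrogens), \code{degree}, \code{hybridization} (one of
#'   \code{"sp","sp2","sp3","other"}), and \code{bonds}, a data.frame with
#'   columns \code{i}, \code{j}, \code{order}, \code{aromatic},
#'   \code{in_ring}.
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  key <- smiles
  hit <- get0(key, envir = .mol_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))[[1]]),
    error = function(e) NULL
  )
  ok <- FALSE
  if (!is.null(sdf)) {
    ab <- ChemmineR::atomblock(sdf)
    # connection tables without bonds come back mangled (rownames "0");
    # require well-formed Element_index row labels
    ok <- is.matrix(ab) && nrow(ab) >= 1 &&
      all(grepl("^[A-Za-z]+_[0-9]+$", rownames(ab)))
  }
  if (!ok) {
    mol <- .parse_single_atom(smiles)
    if (is.null(mol))
      stop("SMILES failed to parse: '", smiles, "'", call. = FALSE)
    assign(key, mol, envir = .mol_cache)
    return(mol)
  }

  ab <- ChemmineR::atomblock(sdf)
  n <- nrow(ab)
  elements <- sub("_.*$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) .mdl_charge(ab[, "C6"]) else integer(n)

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0), byrow = TRUE)
  nb <- nrow(bb)
  bonds <- data.frame(
    i = if (nb) as.integer(bb[, 1]) else integer(0),
    j = if (nb) as.integer(bb[, 2]) else integer(0),
    order = if (nb) as.integer(bb[, 3]) else integer(0)
  )

  # ring membership + aromatic perception
  in_ring_atom <- rep(FALSE, n)
  aromatic_atom <- rep(FALSE, n)
  if (nb) {
    rng <- tryCatch(
      ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_idx <- lapply(rng$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    for (k in seq_along(ring_idx)) {
      in_ring_atom[ring_idx[[k]]] <- TRUE
      if (isTRUE(rng$AROMATIC[[k]])) aromatic_atom[ring_idx[[k]]] <- TRUE
    }
  }
  bonds$aromatic <- aromatic_atom[bonds$i] & aromatic_atom[bonds$j]
  bonds$in_ring <- in_ring_atom[bonds$i] & in_ring_atom[bonds$j]
  # ring closure check: a bond is in a ring only if both atoms share a ring;
  # the conservative both-endpoints test suffices for fused small-ring systems
  # used here.

  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)

  val_sum <- rep(0, n)
  if (nb) {
    for (r in seq_len(nb)) {
      val_sum[bonds$i[r]] <- val_sum[bonds$i[r]] + bonds$order[r]
      val_sum[bonds$j[r]] <- val_sum[bonds$j[r]] + bonds$order[r]
    }
  }
  dv <- .default_valence[elements]
  dv[is.na(dv)] <- val_sum[is.na(dv)]   # unknown elements: no implicit H
  # charge shifts the bonding capacity of N/P up and O/S down symmetrically
  adj <- ifelse(elements %in% c("N", "P"), charge,
         ifelse(elements %in% c("O", "S"), charge, 0L))
  n_h <- pmax(0L, as.integer(dv + adj - val_sum))

  has_triple <- rep(FALSE, n)
  n_double <- rep(0L, n)
  if (nb) {
    for (r in seq_len(nb)) {
      if (bonds$order[r] == 3L) has_triple[c(bonds$i[r], bonds$j[r])] <- TRUE
      if (bonds$order[r] == 2L) {
        n_double[bonds$i[r]] <- n_double[bonds$i[r]] + 1L
        n_double[bonds$j[r]] <- n_double[bonds$j[r]] + 1L
      }
    }
  }
  hybridization <- ifelse(has_triple | n_double >= 2L, "sp",
                   ifelse(aromatic_atom | n_double == 1L, "sp2", "sp3"))

  mol <- list(
    smiles = smiles, elements = elements, charge = charge,
    aromatic_atom = aromatic_atom, in_ring_atom = in_ring_atom,
    n_h = n_h, degree = degree, hybridization = hybridization,
    bonds = bonds
  )
  assign(key, mol, envir = .mol_cache)
  mol
}

# Single heavy atoms ("C", "[Se]", "[O-]", "[NH4+]") bypass the SDF reader,
# whose connection-table round trip requires at least one bond.
.parse_single_atom <- function(smiles) {
  bare <- "^(Br|Cl|B|C|N|O|F|P|S|I|b|c|n|o|p|s)$"
  brak <- "^\\[([A-Z][a-z]?|[a-z])(H([0-9]*))?(([+-])([0-9]*)|(\\+\\+)|(--))?\\]$"
  if (grepl(bare, smiles)) {
    elem_raw <- smiles
    n_h_explicit <- NA_integer_
    charge <- 0L
  } else if (grepl(brak, smiles)) {
    m <- regmatches(smiles, regexec(brak, smiles))[[1]]
    elem_raw <- m[2]
    n_h_explicit <- if (nzchar(m[3]))
      if (nzchar(m[4])) as.integer(m[4]) else 1L else 0L
    charge <- if (nzchar(m[6]))
      as.integer(paste0(m[6], if (nzchar(m[7])) m[7] else "1"))
    else if (nzchar(m[8])) 2L else if (nzchar(m[9])) -2L else 0L
  } else return(NULL)
  elem <- paste0(toupper(substr(elem_raw, 1, 1)), substring(elem_raw, 2))
  n_h <- if (!is.na(n_h_explicit)) n_h_explicit else {
    dv <- .default_valence[elem]
    if (is.na(dv)) 0L else as.integer(dv)
  }
  list(
    smiles = smiles, elements = elem, charge = charge,
    aromatic_atom = FALSE, in_ring_atom = FALSE,
    n_h = n_h, degree = 0L, hybridization = "sp3",
    bonds = data.frame(i = integer(0), j = integer(0), order = integer(0),
                       aromatic = logical(0), in_ring = logical(0))
  )
}

#' Validate that a SMILES string parses
#' @param smiles a single SMILES string.
#' @return TRUE/FALSE invisibly usable in filters.
#' @export
smiles_parses <- function(smiles) {
  !inherits(tryCatch(parse_molecule(smiles), error = function(e) e), "error")
}
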