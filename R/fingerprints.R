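# Circular (Morgan/ECFP-style) fingerprints and a differential reaction
# fingerprint, built on the parsed molecular graphs.
#
# Hashing uses a polynomial rolling hash over a large prime so bit positions
# are exact in double arithmetic and identical across platforms. Bit-level
# equality with other toolkits' ECFP implementations is not promised; tests
# rely on structural properties and self-consistency.

.FP_PRIME <- 2147483647   # 2^31 - 1
.FP_SEED <- 1013904223    # documented hash seed; fixed for reproducibility

.stable_hash <- function(s) {
  h <- .FP_SEED
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% .FP_PRIME
  h
}

# adjacency as list of (neighbor, bond order/aromatic code) per atom
.adjacency <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  b <- mol$bonds
  code <- ifelse(b$aromatic, 4L, pmin(b$order, 3L))
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- rbind(adj[[b$i[r]]], c(b$j[r], code[r]))
    adj[[b$j[r]]] <- rbind(adj[[b$j[r]]], c(b$i[r], code[r]))
  }
  adj
}

.atom_invariant <- function(mol) {
  paste(mol$elements, mol$degree, mol$n_h, mol$charge,
        as.integer(mol$aromatic_atom), as.integer(mol$in_ring_atom),
        sep = ",")
}

# Hashed identifiers of all circular environments up to `radius`.
# An identifier is emitted for radius r > 0 only when the environment still
# grew relative to r - 1, mirroring the usual ECFP termination rule.
.morgan_ids <- function(mol, radius) {
  n <- length(mol$elements)
  adj <- .adjacency(mol)
  ids <- vapply(.atom_invariant(mol), .stable_hash, numeric(1),
                USE.NAMES = FALSE)
  out <- ids
  env_size <- rep(1L, n)
  reached <- lapply(seq_len(n), function(i) i)
  for (r in seq_len(radius)) {
    new_ids <- ids
    new_reached <- reached
    grew <- rep(FALSE, n)
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      if (is.null(nb)) next
      parts <- sort(paste0(nb[, 2], ":", format(ids[nb[, 1]], scientific = FALSE)))
      new_ids[v] <- .stable_hash(paste0(r, "|", format(ids[v], scientific = FALSE),
                                        "|", paste(parts, collapse = "|")))
      nbr_sets <- unique(unlist(reached[nb[, 1]]))
      merged <- union(reached[[v]], nbr_sets)
      grew[v] <- length(merged) > env_size[v]
      new_reached[[v]] <- merged
    }
    ids <- new_ids
    reached <- new_reached
    env_size <- lengths(reached)
    out <- c(out, ids[grew])
  }
  out
}

#' Morgan fingerprint bit indices of one molecule
#'
#' @param smiles SMILES string.
#' @param radius circular radius (default 2).
#' @param n_bits fingerprint length.
#' @return integer vector of set bit positions (1-based, may repeat).
#' @export
morgan_bits <- function(smiles, radius = 2L, n_bits = 512L) {
  key <- paste0("fp|", smiles, "|", radius, "|", n_bits)
  hit <- get0(key, envir = .mol_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  ids <- .morgan_ids(parse_molecule(smiles), radius)
  bits <- as.integer(ids %% n_bits) + 1L
  assign(key, bits, envir = .mol_cache)
  bits
}

#' Morgan reaction fingerprints for a reaction list
#'
#' Computes a hashed circular fingerprint per component and combines the
#' per-role blocks either by concatenation (order-sensitive, width
#' \code{bits_per_component * n_roles}, binary) or by summation (width
#' \code{bits_per_component}, non-negative integer counts).
#'
#' @param reactions list of \code{reaction} objects.
#' @param radius circular radius (default 2, as in ECFP4).
#' @param bits_per_component fingerprint length per component (default 512).
#' @param mode \code{"concat"} or \code{"sum"}.
#' @return a \code{feature_matrix}: numeric matrix with attributes
#'   \code{featurizer_tag} and per-column provenance.
#' @export
morgan_reaction_fp <- function(reactions, radius = 2L,
                               bits_per_component = 512L,
                               mode = c("concat", "sum")) {
  mode <- match.arg(mode)
  roles <- reaction_roles(reactions)
  n <- length(reactions)
  d <- if (mode == "concat") bits_per_component * length(roles) else bits_per_component
  m <- matrix(0, n, d)
  for (ri in seq_along(reactions)) {
    rx <- reactions[[ri]]
    for (k in seq_along(roles)) {
      smi <- rx$components[[roles[k]]]
      bits <- tryCatch(morgan_bits(smi, radius, bits_per_component),
                       error = function(e)
                         stop("featurization error for reaction '", rx$id,
                              "', role '", roles[k], "': ",
                              conditionMessage(e), call. = FALSE))
      if (mode == "concat") {
        m[ri, (k - 1L) * bits_per_component + unique(bits)] <- 1
      } else {
        tb <- table(unique(bits))  # per-component presence, summed over roles
        idx <- as.integer(names(tb))
        m[ri, idx] <- m[ri, idx] + as.integer(tb)
      }
    }
  }
  feature_matrix(m, paste0("morgan_", mode))
}

#' Construct a feature matrix with provenance
#' @param values numeric matrix, no NaN/Inf.
#' @param featurizer_tag provenance tag.
#' @return the matrix with class \code{feature_matrix}.
#' @export
feature_matrix <- function(values, featurizer_tag) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(values, featurizer_tag = featurizer_tag,
            class = c("feature_matrix", class(values)))
}

# canonical string of the induced subgraph within distance r of a centre atom:
# iterative label refinement, serialized as sorted atom + bond label multisets
.env_string <- function(mol, adj, centre, radius) {
  dist <- rep(Inf, length(mol$elements))
  dist[centre] <- 0
  frontier <- centre
  for (d in seq_len(radius)) {
    nxt <- unique(unlist(lapply(frontier, function(v)
      if (!is.null(adj[[v]])) adj[[v]][, 1])))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  atoms <- which(is.finite(dist))
  labels <- .atom_invariant(mol)[atoms]
  pos <- match(seq_along(mol$elements), atoms)
  b <- mol$bonds
  keep <- !is.na(pos[b$i]) & !is.na(pos[b$j])
  bi <- pos[b$i[keep]]; bj <- pos[b$j[keep]]
  bc <- ifelse(b$aromatic, 4L, pmin(b$order, 3L))[keep]
  for (it in seq_len(radius + 1L)) {
    nbl <- vector("list", length(atoms))
    for (e in seq_along(bi)) {
      nbl[[bi[e]]] <- c(nbl[[bi[e]]], paste0(bc[e], "~", labels[bj[e]]))
      nbl[[bj[e]]] <- c(nbl[[bj[e]]], paste0(bc[e], "~", labels[bi[e]]))
    }
    labels <- vapply(seq_along(atoms), function(v)
      paste0(labels[v], "(", paste(sort(nbl[[v]]), collapse = ";"), ")"),
      character(1))
    labels <- vapply(labels, .stable_hash, numeric(1), USE.NAMES = FALSE)
    labels <- format(labels, scientific = FALSE)
  }
  bond_lab <- vapply(seq_along(bi), function(e)
    paste0(bc[e], "~", paste(sort(c(labels[bi[e]], labels[bj[e]])),
                             collapse = "~")), character(1))
  paste0("A[", paste(sort(labels), collapse = ","), "]B[",
         paste(sort(bond_lab), collapse = ","), "]")
}

#' Differential reaction fingerprint
#'
#' Enumerates canonical circular-substructure strings up to \code{radius}
#' around every atom of every molecule on the reactant and product sides
#' (each side treated as a set), takes the symmetric difference of the two
#' string sets, and hashes each surviving substructure into
#' \code{[0, n_bits)} with a stable seeded hash.
#'
#' @param reaction_smiles reaction SMILES \code{"reactants>>products"} with
#'   \code{.}-separated molecules per side.
#' @param radius maximum environment radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return binary numeric vector of length \code{n_bits}; all-zero when the
#'   two substructure sets coincide.
#' @export
drfp_reaction_fp <- function(reaction_smiles, radius = 2L, n_bits = 2048L) {
  parts <- strsplit(reaction_smiles, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
    stop("reaction SMILES must be 'reactants>>products' with both sides ",
         "non-empty: '", reaction_smiles, "'", call. = FALSE)
  side_set <- function(side) {
    mols <- strsplit(side, ".", fixed = TRUE)[[1]]
    mols <- mols[nzchar(mols)]
    subs <- character(0)
    for (smi in mols) {
      mol <- parse_molecule(smi)
      adj <- .adjacency(mol)
      for (a in seq_along(mol$elements))
        for (r in 0:radius)
          subs <- c(subs, .env_string(mol, adj, a, r))
    }
    unique(subs)
  }
  left <- side_set(parts[1])
  right <- side_set(parts[2])
  diff <- c(setdiff(left, right), setdiff(right, left))
  v <- numeric(n_bits)
  if (length(diff)) {
    idx <- vapply(diff, .stable_hash, numeric(1), USE.NAMES = FALSE) %% n_bits
    v[as.integer(idx) + 1L] <- 1
  }
  v
}

#' Concatenate per-role descriptor vectors
#'
#' @param reactions list of \code{reaction} objects.
#' @param tables named list role -> data.frame/matrix of descriptors with
#'   rownames = component SMILES (or a column named \code{component}).
#' @return a \code{feature_matrix} of width = sum of per-role widths.
#' @export
descriptor_concat <- function(reactions, tables) {
  roles <- reaction_roles(reactions)
  stopifnot(all(roles %in% names(tables)))
  tabs <- lapply(roles, function(role) {
    t <- tables[[role]]
    if (is.data.frame(t) && "component" %in% names(t)) {
      rn <- t$component
      t <- as.matrix(t[setdiff(names(t), "component")])
      rownames(t) <- rn
    } else t <- as.matrix(t)
    if (is.null(rownames(t)))
      stop("descriptor table for role '", role,
           "' has no component identifiers", call. = FALSE)
    storage.mode(t) <- "double"
    if (any(!is.finite(t)))
      stop("descriptor table for role '", role,
           "' contains non-finite values (ragged or non-numeric input)",
           call. = FALSE)
    t
  })
  names(tabs) <- roles
  rows <- lapply(reactions, function(rx) {
    unlist(lapply(roles, function(role) {
      comp <- rx$components[[role]]
      t <- tabs[[role]]
      i <- match(comp, rownames(t))
      if (is.na(i))
        stop("descriptor lookup failed for reaction '", rx$id, "': role '",
             role, "', component '", comp, "' not in its table",
             call. = FALSE)
      t[i, ]
    }), use.names = FALSE)
  })
  feature_matrix(do.call(rbind, rows), "descriptor")
}
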