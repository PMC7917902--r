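## Dendrimer topology construction.
##
## All four homologous series share the same architecture: a central Si atom
## carrying f_c dendrons; each dendron is a spacer leading to a three-functional
## branching point Si(CH3) with two outgoing spacers, repeated to depth G; the
## depth-G branching Si carry two terminal segments each.  The series differ in
## spacer and end-group chemistry:
##   C4, C3  spacer -(CH2)3-,          butyl -(CH2)3-CH3 ends, f_c = 4 / 3
##   S       spacer -O-,               methyl ends (Si(CH3)3 caps)
##   L       spacer -O-Si(CH3)2-O-,    methyl ends (Si(CH3)3 caps)

## united-atom masses in Da
UA_MASSES <- c(Si = 28.086, O = 15.999, CH2 = 14.027, CH3 = 15.035)

DENDRIMER_SERIES <- c("C4", "C3", "S", "L")

#' Specify a dendrimer
#'
#' @param series one of `"C4"`, `"C3"` (carbosilane, core functionality 4 / 3),
#'   `"S"` (siloxane, single-oxygen spacer) or `"L"` (siloxane,
#'   -O-Si(CH3)2-O- spacer).
#' @param generation branching depth G (>= 1). Generations 4-7 are the
#'   full-scale regime; low generations are used for desk-scale runs.
#' @param core_functionality number of dendrons on the core Si. Fixed at 4 for
#'   C4 and 3 for C3; configurable (3 or 4, default 3) for the siloxane series,
#'   whose core structure is not uniquely determined by the chemistry.
#' @param siloxane_o_charge partial charge (e) on siloxane oxygens; each bonded
#'   Si receives the compensating `-siloxane_o_charge/2` so the molecule is
#'   exactly neutral. Carbosilane atoms are uncharged.
#' @return an object of class `dendrimer_spec`.
#' @export
dendrimer_spec <- function(series, generation, core_functionality = NULL,
                           siloxane_o_charge = -0.2) {
  series <- match.arg(series, DENDRIMER_SERIES)
  if (!is.numeric(generation) || length(generation) != 1L ||
      generation < 1 || generation != round(generation)) {
    stop("generation must be a single integer >= 1")
  }
  generation <- as.integer(generation)
  fc_fixed <- switch(series, C4 = 4L, C3 = 3L, NULL)
  if (is.null(core_functionality)) {
    core_functionality <- if (is.null(fc_fixed)) 3L else fc_fixed
  }
  core_functionality <- as.integer(core_functionality)
  if (!core_functionality %in% c(3L, 4L)) {
    stop("core_functionality must be 3 or 4")
  }
  if (!is.null(fc_fixed) && core_functionality != fc_fixed) {
    stop(sprintf("series %s has core functionality %d by definition",
                 series, fc_fixed))
  }
  structure(
    list(series = series, generation = generation,
         core_functionality = core_functionality,
         siloxane_o_charge = siloxane_o_charge),
    class = "dendrimer_spec")
}

#' @export
print.dendrimer_spec <- function(x, ...) {
  cat(sprintf("dendrimer spec: %s series, generation %d, core functionality %d\n",
              x$series, x$generation, x$core_functionality))
  invisible(x)
}

element_of <- function(type) c(Si = "Si", O = "O", CH2 = "C", CH3 = "C")[type]

#' Build the united-atom topology of a dendrimer
#'
#' Expands a [dendrimer_spec()] into a tree of united atoms with bond, angle
#' and (for the carbosilane series) dihedral lists, structural-layer labels and
#' partial charges.  Atom numbering is deterministic (depth-first from the
#' core), so two calls with the same spec give identical topologies.
#'
#' @param spec a [dendrimer_spec()].
#' @return an object of class `molecular_topology` with elements `spec`,
#'   `atoms` (data frame: `id`, `type`, `element`, `mass`, `charge`, `layer`,
#'   `role`, `depth`, `parent`), `bonds`, `angles`, `dihedrals` and `N`.
#' @export
build_topology <- function(spec) {
  if (!inherits(spec, "dendrimer_spec")) stop("spec must be a dendrimer_spec")
  series <- spec$series
  G <- spec$generation
  fc <- spec$core_functionality
  carbosilane <- series %in% c("C4", "C3")

  ## grow-able columns; N is a few thousand at most so append cost is fine
  type <- character(0); parent <- integer(0)
  role <- character(0); depth <- integer(0)

  add_atom <- function(ty, par, ro, dep = NA_integer_) {
    id <- length(type) + 1L
    type[id] <<- ty; parent[id] <<- par; role[id] <<- ro; depth[id] <<- dep
    id
  }

  ## adds one spacer outgoing from `from`; returns the far-end atom id
  add_spacer <- function(from) {
    if (carbosilane) {
      a <- add_atom("CH2", from, "spacer")
      b <- add_atom("CH2", a, "spacer")
      add_atom("CH2", b, "spacer")
    } else if (series == "S") {
      add_atom("O", from, "spacer")
    } else { # L: -O-Si(CH3)2-O-
      o1 <- add_atom("O", from, "spacer")
      si <- add_atom("Si", o1, "spacer")
      add_atom("CH3", si, "spacer")
      add_atom("CH3", si, "spacer")
      add_atom("O", si, "spacer")
    }
  }

  add_terminal <- function(from) {
    if (carbosilane) { # butyl -(CH2)3-CH3
      a <- add_atom("CH2", from, "terminal")
      b <- add_atom("CH2", a, "terminal")
      d <- add_atom("CH2", b, "terminal")
      add_atom("CH3", d, "terminal")
    } else {
      add_atom("CH3", from, "terminal")
    }
    invisible(NULL)
  }

  grow <- function(parent_si, k) {
    end <- add_spacer(parent_si)
    si <- add_atom("Si", end, "branch", k)
    add_atom("CH3", si, "methyl")
    if (k < G) {
      grow(si, k + 1L)
      grow(si, k + 1L)
    } else {
      add_terminal(si)
      add_terminal(si)
    }
  }

  core <- add_atom("Si", NA_integer_, "core", 0L)
  for (i in seq_len(fc)) grow(core, 1L)

  N <- length(type)
  element <- unname(element_of(type))
  mass <- unname(UA_MASSES[type])

  ## bonds from the tree
  child <- which(!is.na(parent))
  bonds <- data.frame(i = parent[child], j = child)
  bkey <- function(e1, e2) {
    s <- t(apply(cbind(e1, e2), 1L, sort))
    paste(s[, 1L], s[, 2L], sep = "-")
  }
  bonds$type <- bkey(element[bonds$i], element[bonds$j])

  ## adjacency for angle/dihedral enumeration
  adj <- vector("list", N)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }

  ang <- list()
  for (j in seq_len(N)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      ang[[length(ang) + 1L]] <- cbind(cmb[1L, ], j, cmb[2L, ])
    }
  }
  ang <- do.call(rbind, ang)
  ends <- cbind(element[ang[, 1L]], element[ang[, 3L]])
  ends <- t(apply(ends, 1L, sort))
  angles <- data.frame(i = ang[, 1L], j = ang[, 2L], k = ang[, 3L],
                       type = paste(ends[, 1L], element[ang[, 2L]], ends[, 2L],
                                    sep = "-"))

  ## dihedrals (carbosilane series only): all bonded quadruples i-j-k-l
  dihedrals <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                          l = integer(0), type = character(0))
  if (carbosilane) {
    quads <- list()
    for (r in seq_len(nrow(bonds))) {
      j <- bonds$i[r]; k <- bonds$j[r]
      ni <- setdiff(adj[[j]], k); nl <- setdiff(adj[[k]], j)
      if (length(ni) && length(nl)) {
        g <- expand.grid(i = ni, l = nl)
        quads[[length(quads) + 1L]] <- cbind(g$i, j, k, g$l)
      }
    }
    q <- do.call(rbind, quads)
    dihedrals <- data.frame(i = q[, 1L], j = q[, 2L], k = q[, 3L], l = q[, 4L],
                            type = "generic")
  }

  ## partial charges: siloxanes only, exactly neutralized through bonded Si
  charge <- numeric(N)
  if (!carbosilane) {
    qo <- spec$siloxane_o_charge
    charge[type == "O"] <- qo
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (type[i] == "O" && type[j] == "Si") charge[j] <- charge[j] - qo / 2
      if (type[j] == "O" && type[i] == "Si") charge[i] <- charge[i] - qo / 2
    }
  }

  topo <- structure(
    list(spec = spec,
         atoms = data.frame(id = seq_len(N), type = type, element = element,
                            mass = mass, charge = charge,
                            layer = NA_integer_, role = role, depth = depth,
                            parent = parent),
         bonds = bonds, angles = angles, dihedrals = dihedrals, N = N),
    class = "molecular_topology")
  assign_layers(topo)
}

#' Assign structural-layer labels
#'
#' A structural layer k groups the branching Si atoms at topological depth k
#' (number of branching points between them and the core, inclusive) together
#' with their methyls and outgoing spacers; layer 0 is the core Si plus the f_c
#' spacers emanating from it; layer G additionally holds the terminal segments.
#' Every atom receives exactly one layer index in `0..G`.
#'
#' @param topology a `molecular_topology`.
#' @return the topology with the `layer` column filled in.
#' @export
assign_layers <- function(topology) {
  if (!inherits(topology, "molecular_topology")) {
    stop("topology must be a molecular_topology")
  }
  at <- topology$atoms
  anchor <- at$role %in% c("core", "branch")
  layer <- integer(topology$N)
  for (i in seq_len(topology$N)) {
    j <- i
    while (!anchor[j]) j <- at$parent[j]
    layer[i] <- at$depth[j]
  }
  topology$atoms$layer <- layer
  topology
}

#' Per-layer atom counts
#'
#' @param topology a `molecular_topology` with layers assigned.
#' @return data frame with `layer` and `n_atoms`.
#' @export
layer_counts <- function(topology) {
  tb <- table(topology$atoms$layer)
  data.frame(layer = as.integer(names(tb)), n_atoms = as.integer(tb))
}

#' @export
print.molecular_topology <- function(x, ...) {
  cat(sprintf("%s G%d dendrimer: %d united atoms, %d bonds, %d angles, %d dihedrals, layers 0-%d\n",
              x$spec$series, x$spec$generation, x$N, nrow(x$bonds),
              nrow(x$angles), nrow(x$dihedrals), max(x$atoms$layer)))
  invisible(x)
}

#' Dump a topology to JSON
#'
#' Writes atoms (with layer labels), bonds, angles and dihedrals so the
#' structure can be consumed outside R.
#'
#' @param topology a `molecular_topology`.
#' @param path output file.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    spec = topology$spec[c("series", "generation", "core_functionality")],
    n_atoms = topology$N,
    atoms = topology$atoms[, c("id", "type", "mass", "charge", "layer")],
    bonds = topology$bonds,
    angles = topology$angles,
    dihedrals = topology$dihedrals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
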