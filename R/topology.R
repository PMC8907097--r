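## Topology model: species-tagged molecules with nonbonded parameters.
##
## A topology is delivered as a JSON document (not a force-field file):
##   {
##     "molecule_types": {
##       "CBZ": {"atoms": [{"name": "C1", "charge": -0.1, "sigma": 3.4,
##                          "epsilon": 0.086, "mass": 12.011}, ...]},
##       "WAT": {"atoms": [...]}, "NA": {...}, "CL": {...}
##     },
##     "molecules": [{"type": "CBZ", "count": 1}, {"type": "WAT", "count": 500},
##                   {"type": "NA", "count": 9}, {"type": "CL", "count": 9}]
##   }
## plus a species assignment mapping molecule-type names to tags
## {solute, wat, cation, anion}.

#' Construct a mixture topology
#'
#' Builds the package's topology model from per-type atom tables and a list of
#' molecule blocks.  The solvent is a mixture of water (`wat`), one monoatomic
#' cation species (`cation`) and one monoatomic anion species (`anion`) around
#' exactly one rigid solute (`solute`).
#'
#' Invariants enforced: every molecule-type name must be mapped to a species
#' tag; ions must be monoatomic; water must have at least three atoms and a
#' designated center atom (the oxygen, by GIST convention); there must be
#' exactly one solute molecule.
#'
#' @param molecule_types named list; each element a list with an `atoms`
#'   data.frame/list carrying `name`, `charge` (e), `sigma` (Angstrom),
#'   `epsilon` (kcal/mol), `mass` (amu).
#' @param molecules list of blocks `list(type =, count =)`, expanded in order.
#' @param species named character vector mapping type names to
#'   `"solute"`, `"wat"`, `"cation"` or `"anion"`.
#' @param water_center name of the water center atom (default `"O"`); if no
#'   atom of that name exists the heaviest atom is used.
#' @return An object of class `mixture_topology`: list with `atoms`
#'   (data.frame: `index`, `mol`, `type`, `species`, `name`, `charge`,
#'   `sigma`, `epsilon`, `mass`), `mol` (data.frame: `mol`, `type`, `species`,
#'   `first`, `last`, `natoms`, `center_atom`), `counts` (named molecule
#'   counts), `solute_heavy` (atom indices), `n_atoms`.
#' @seealso [load_topology()] to read the JSON document from disk.
#' @export
mixture_topology <- function(molecule_types, molecules, species,
                             water_center = "O") {
  stopifnot(is.list(molecule_types), is.list(molecules))
  species <- unlist(species)
  type_names <- vapply(molecules, function(m) as.character(m$type), "")
  unmapped <- setdiff(unique(type_names), names(species))
  if (length(unmapped) > 0L)
    stop("unmapped species for molecule type(s): ",
         paste(unmapped, collapse = ", "))
  bad_tag <- setdiff(unique(as.character(species)),
                     c("solute", .SPECIES))
  if (length(bad_tag) > 0L)
    stop("unknown species tag(s): ", paste(bad_tag, collapse = ", "))

  atom_tab <- lapply(molecule_types, function(mt) {
    at <- mt$atoms
    if (!is.data.frame(at)) at <- do.call(rbind, lapply(at, as.data.frame))
    need <- c("name", "charge", "sigma", "epsilon", "mass")
    miss <- setdiff(need, names(at))
    if (length(miss) > 0L)
      stop("atom table missing field(s): ", paste(miss, collapse = ", "))
    at
  })

  mol_rows <- list(); atom_rows <- list()
  mol_id <- 0L; atom_id <- 0L
  for (blk in molecules) {
    tname <- as.character(blk$type)
    count <- as.integer(blk$count)
    tag <- as.character(species[[tname]])
    at <- atom_tab[[tname]]
    na <- nrow(at)
    if (tag %in% c("cation", "anion") && na != 1L)
      stop("ion must be monoatomic: type '", tname, "' has ", na, " atoms")
    if (tag == "wat" && na < 3L)
      stop("water must have >= 3 atoms: type '", tname, "' has ", na)
    center_local <- 1L
    if (tag == "wat") {
      hit <- which(at$name == water_center)
      center_local <- if (length(hit) > 0L) hit[1L] else which.max(at$mass)
    }
    for (i in seq_len(count)) {
      mol_id <- mol_id + 1L
      first <- atom_id + 1L
      atom_rows[[mol_id]] <- data.frame(
        index = atom_id + seq_len(na), mol = mol_id, type = tname,
        species = tag, name = as.character(at$name),
        charge = as.numeric(at$charge), sigma = as.numeric(at$sigma),
        epsilon = as.numeric(at$epsilon), mass = as.numeric(at$mass),
        stringsAsFactors = FALSE)
      atom_id <- atom_id + na
      mol_rows[[mol_id]] <- data.frame(
        mol = mol_id, type = tname, species = tag, first = first,
        last = atom_id, natoms = na, center_atom = first + center_local - 1L,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atom_rows)
  mol <- do.call(rbind, mol_rows)
  rownames(atoms) <- rownames(mol) <- NULL

  counts <- c(solute = sum(mol$species == "solute"),
              wat    = sum(mol$species == "wat"),
              cation = sum(mol$species == "cation"),
              anion  = sum(mol$species == "anion"))
  if (counts[["solute"]] != 1L)
    stop("topology must contain exactly one solute molecule, found ",
         counts[["solute"]])
  sol <- atoms$species == "solute"
  solute_heavy <- atoms$index[sol & atoms$mass > 2.0]

  structure(list(atoms = atoms, mol = mol, counts = counts,
                 solute_heavy = solute_heavy, n_atoms = nrow(atoms),
                 water_center = water_center),
            class = "mixture_topology")
}

#' Read a topology JSON document
#'
#' Parses the package's JSON topology format (molecule types with nonbonded
#' parameters plus an ordered molecule list) and assigns species tags from a
#' name-to-tag mapping.
#'
#' @param path path to the JSON file.
#' @param species named character vector or list mapping molecule-type names
#'   to species tags (`solute`/`wat`/`cation`/`anion`).  If `NULL`, a
#'   `"species"` entry inside the JSON document is used.
#' @param water_center water center atom name, see [mixture_topology()].
#' @return A [mixture_topology()] object.  Per-species molecule counts are
#'   reported via `message()`.
#' @export
load_topology <- function(path, species = NULL, water_center = "O") {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(species)) species <- unlist(doc$species)
  if (is.null(species)) stop("no species assignment given")
  mols <- doc$molecules
  if (is.data.frame(mols))
    mols <- lapply(seq_len(nrow(mols)),
                   function(i) list(type = mols$type[i], count = mols$count[i]))
  mt <- lapply(doc$molecule_types, function(x) list(atoms = x$atoms))
  topo <- mixture_topology(mt, mols, species, water_center)
  message("topology: ", paste(names(topo$counts), topo$counts,
                              sep = "=", collapse = ", "))
  topo
}

#' Write a topology JSON document
#'
#' Inverse of [load_topology()]: serializes molecule types, the ordered
#' molecule list and the species assignment.
#'
#' @param topology a [mixture_topology()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "mixture_topology"))
  ## compress consecutive molecules of equal type back into blocks
  types <- topology$mol$type
  r <- rle(types)
  blocks <- data.frame(type = r$values, count = r$lengths,
                       stringsAsFactors = FALSE)
  mt <- list()
  for (tn in unique(types)) {
    m1 <- topology$mol[topology$mol$type == tn, ][1L, ]
    at <- topology$atoms[m1$first:m1$last,
                         c("name", "charge", "sigma", "epsilon", "mass")]
    rownames(at) <- NULL
    mt[[tn]] <- list(atoms = at)
  }
  sp <- lapply(split(topology$mol$species, topology$mol$type), `[`, 1L)
  doc <- list(molecule_types = mt, molecules = blocks, species = sp)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.mixture_topology <- function(x, ...) {
  cat("mixture_topology:", x$n_atoms, "atoms,",
      nrow(x$mol), "molecules\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "), "\n")
  cat("  solute heavy atoms:", length(x$solute_heavy), "\n")
  invisible(x)
}

## Internal: species code per molecule (0 solute, 1 wat, 2 cation, 3 anion).
.species_code <- function(topology) {
  match(topology$mol$species, c("solute", .SPECIES)) - 1L
}

## Internal: indices of solvent molecules (everything but the solute).
.solvent_mols <- function(topology) which(topology$mol$species != "solute")
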