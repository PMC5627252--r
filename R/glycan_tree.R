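# Glycoform definitions. Residue indices follow the high-mannose numbering
# used throughout: GlcNAc1 is the asparagine-linked root, GlcNAc2 and the
# beta-mannose (3) complete the chitobiose-mannose core, one arm carries
# mannoses 4-(5-6, 7) and the other 8-9-10. Man5 is Man8 with residues
# 6, 9 and 10 removed; the single-GlcNAc form keeps only the root.
.GLYCOFORMS <- list(
  Man8 = list(
    indices = 1:10,
    parents = c(NA, 1, 2, 3, 4, 5, 4, 3, 8, 9),
    names = c("GlcNAc", "GlcNAc", rep("Man", 8)),
    terminals = c(6, 7, 10)
  ),
  Man5 = list(
    indices = c(1, 2, 3, 4, 5, 7, 8),
    parents = c(NA, 1, 2, 3, 4, 4, 3),
    names = c("GlcNAc", "GlcNAc", rep("Man", 5)),
    terminals = c(5, 7, 8)
  ),
  GlcNAc = list(
    indices = 1,
    parents = NA,
    names = "GlcNAc",
    terminals = 1
  ),
  N297Q = list(
    indices = integer(0),
    parents = integer(0),
    names = character(0),
    terminals = integer(0)
  )
)

#' Glycoform definition table
#'
#' @param glycoform one of `"Man8"`, `"Man5"`, `"GlcNAc"`, `"N297Q"`.
#' @return list with `indices`, `parents`, `names`, `terminals`.
#' @export
glycoform_definition <- function(glycoform) {
  if (!glycoform %in% names(.GLYCOFORMS))
    stop("unknown glycoform '", glycoform, "'; known: ",
         paste(names(.GLYCOFORMS), collapse = ", "))
  .GLYCOFORMS[[glycoform]]
}

#' Construct a per-chain glycan tree
#'
#' @param chain_id chain the glycan is attached to.
#' @param indices glycan residue indices (1..10 numbering).
#' @param parents parent index per residue (`NA` for the root).
#' @param names residue names (`"GlcNAc"` / `"Man"`).
#' @param terminals terminal (non-reducing end) residue indices.
#' @param residue_keys residue keys into the host `fc_system`, parallel to
#'   `indices` (optional until the tree is bound to a structure).
#' @return an object of class `fc_glycan_tree`.
#' @export
glycan_tree <- function(chain_id, indices, parents, names, terminals,
                        residue_keys = NULL) {
  if (anyDuplicated(indices)) stop("duplicate glycan indices")
  if (length(indices) > 0) {
    if (indices[1] != 1 || !is.na(parents[1]))
      stop("glycan tree must be rooted at residue 1 (GlcNAc1)")
    known <- parents[-1]
    if (any(!known %in% indices))
      stop("parent links reference unknown residues")
    # acyclicity: walk each residue to the root
    pmap <- setNames(parents, indices)
    for (i in indices) {
      seen <- integer(0)
      j <- i
      while (!is.na(pmap[[as.character(j)]])) {
        if (j %in% seen) stop("cycle in glycan tree at residue ", i)
        seen <- c(seen, j)
        j <- pmap[[as.character(j)]]
      }
    }
  }
  if (!all(terminals %in% indices))
    stop("terminal set not a subset of tree residues")
  structure(
    list(chain_id = chain_id, indices = indices, parents = parents,
         residue_names = names, terminals = terminals,
         residue_keys = residue_keys),
    class = "fc_glycan_tree"
  )
}

#' @export
print.fc_glycan_tree <- function(x, ...) {
  cat(sprintf("fc_glycan_tree chain %s: %d residues, terminals {%s}\n",
              x$chain_id, length(x$indices),
              paste(x$terminals, collapse = ",")))
  invisible(x)
}

#' Build glycan trees for a structure and declared glycoform
#'
#' Locates glycan-component residues in each chain and binds them to the
#' declared glycoform's tree. Structure residues are mapped to glycan indices
#' in residue-number order (generators and the conventional glycan numbering
#' both store residue 1 first); an explicit `index_map` may override this
#' when structure numbering is ambiguous.
#'
#' @param system an `fc_system`.
#' @param glycoform `"Man8"`, `"Man5"`, `"GlcNAc"`, `"N297Q"` or
#'   `"Man8/N297Q"` (chain A carries Man8, further chains none).
#' @param index_map optional named list `chain_id -> integer vector` giving
#'   the glycan index of each glycan residue (in residue-number order).
#' @return list of `fc_glycan_tree`, one per glycosylated chain (empty list
#'   for the aglycosylated form).
#' @export
build_glycan_topology <- function(system, glycoform, index_map = NULL) {
  stopifnot(inherits(system, "fc_system"))
  asym <- identical(glycoform, "Man8/N297Q")
  base_form <- if (asym) "Man8" else glycoform
  def <- glycoform_definition(base_form)

  res <- system$residues
  gly <- res[res$component == "glycan", , drop = FALSE]
  chains_with_glycan <- unique(gly$chain_id)
  if (length(def$indices) == 0) {
    if (nrow(gly) > 0)
      stop("glycoform ", glycoform, " declares no glycan but structure has ",
           nrow(gly), " glycan residues in chain(s) ",
           paste(chains_with_glycan, collapse = ", "))
    return(list())
  }

  expected_chains <- if (asym) chains_with_glycan[1] else chains_with_glycan
  if (length(chains_with_glycan) == 0)
    stop("glycoform ", glycoform,
         " declared but no glycan residues found in structure")

  trees <- list()
  for (ch in expected_chains) {
    g <- gly[gly$chain_id == ch, , drop = FALSE]
    g <- g[order(g$residue_number), , drop = FALSE]
    if (nrow(g) != length(def$indices))
      stop("chain ", ch, ": structure has ", nrow(g),
           " glycan residues but glycoform ", base_form, " defines ",
           length(def$indices), " (residues present: ",
           paste(g$residue_number, collapse = ","), ")")
    idx <- if (!is.null(index_map) && !is.null(index_map[[ch]]))
      index_map[[ch]] else sort(def$indices)
    if (!setequal(idx, def$indices))
      stop("chain ", ch, ": index map does not match glycoform ", base_form)
    ord <- order(idx)
    trees[[ch]] <- glycan_tree(
      chain_id = ch,
      indices = idx[ord],
      parents = def$parents[match(idx[ord], def$indices)],
      names = def$names[match(idx[ord], def$indices)],
      terminals = def$terminals,
      residue_keys = g$residue_key[ord]
    )
  }
  trees
}

# Atom indices (heavy by default) of one glycan residue of a bound tree.
glycan_residue_atoms <- function(system, tree, glycan_index,
                                 heavy_only = TRUE) {
  pos <- match(glycan_index, tree$indices)
  if (is.na(pos)) stop("glycan index ", glycan_index, " not in tree")
  key <- tree$residue_keys[pos]
  if (is.null(key) || is.na(key)) stop("tree is not bound to a structure")
  idx <- which(system$atoms$residue_key == key)
  if (heavy_only) idx <- idx[system$atoms$is_heavy[idx]]
  idx
}
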