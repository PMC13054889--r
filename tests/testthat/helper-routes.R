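# Shared builders for route fixtures used across test files.

# linear route: codes root-first, two leaves on the deepest step and one
# leaf plus the intermediate on every other step
chain_route <- function(codes, leaf_stock = "internal", target = "T") {
  build <- function(i) {
    leaf <- mol(paste0("L", i), leaf_stock)
    if (i == length(codes)) {
      rxn(codes[i], leaf, mol(paste0("L", i, "b"), leaf_stock))
    } else {
      inter <- mol(paste0("I", i), "unavailable")
      inter$children <- list(build(i + 1L))
      rxn(codes[i], leaf, inter)
    }
  }
  route_tree(mol(target, reaction = build(1L)))
}

# single-step route with one leaf per entry of leaf_stocks
one_step_route <- function(code, leaf_stocks = "internal", target = "T") {
  r <- rxn(code)
  r$children <- lapply(seq_along(leaf_stocks), function(i)
    mol(paste0("L", i), leaf_stocks[i]))
  route_tree(mol(target, reaction = r))
}

# zero-step route: the target itself is in stock
stock_singleton <- function(id = "T", stock = "internal") {
  route_tree(mol(id, stock))
}

batch_mol <- function(id, trees) list(mol_id = id, trees = trees)
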