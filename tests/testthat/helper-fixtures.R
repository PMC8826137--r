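# Shared fixture builders: everything is generated in code at test time.

# random ultrametric tree with n tips, crown age scaled to `crown`
rand_tree <- function(n, crown = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n, 0.4, 0.1)
  if (!is.null(crown))
    phy$edge.length <- phy$edge.length * crown / decrates::crown_age(phy)
  phy
}

# random geography over n_areas for the tips of phy (no empty ranges)
rand_geography <- function(phy, n_areas, p = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pres <- matrix(rbinom(ape::Ntip(phy) * n_areas, 1, p),
                 ape::Ntip(phy), n_areas,
                 dimnames = list(phy$tip.label, LETTERS[1:n_areas]))
  fix <- rowSums(pres) == 0
  pres[cbind(which(fix), sample.int(n_areas, sum(fix), replace = TRUE))] <- 1L
  decrates::geography_table(pres)
}

# geography from a list of area-index vectors named by tip
geog_from_ranges <- function(ranges, n_areas) {
  pres <- t(vapply(ranges, function(g) {
    v <- integer(n_areas); v[g] <- 1L; v
  }, integer(n_areas)))
  colnames(pres) <- LETTERS[1:n_areas]
  decrates::geography_table(pres)
}

# hand-built two-area history on a fixed two-tip tree, for event counting
manual_history <- function() {
  phy <- ape::read.tree(text = "(t1:2,t2:2);")
  ev <- data.frame(branch = c(1L, 1L, 2L),
                   age = c(1.5, 0.5, 0.25),
                   type = c("expansion", "contraction", "expansion"),
                   area = c("B", "A", "B"),
                   from = c("A", "AB", "A"),
                   to = c("AB", "B", "AB"))
  cl <- data.frame(node = 3L, age = 2, type = "sympatry-copy",
                   anc = "A", left = "A", right = "A")
  structure(list(events = ev, clado = cl,
                 node_state = c("0", "0", "A"),
                 branch_start = c("A", "A", "0"),
                 branch_end = c("B", "AB", "0"),
                 phy = phy, age = decrates::node_ages(phy), ntip = 2L,
                 areas = c("A", "B")),
            class = "bio_history")
}
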