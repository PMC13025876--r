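# Shared synthetic fixtures.

# small end-to-end fixture for fast pipeline tests
make_small_fixture <- function(dir, seed = 23) {
  tl <- make_target_lists(300, 60, 120, 40, seed = seed, dir = dir)
  ov <- gs_intersect(tl$a, tl$b)
  pg <- make_ppi(40, attachment = 2, hub_fraction = 0.3, clique_size = 6,
                 seed = seed + 1, symbols = ov$symbols,
                 path = file.path(dir, "edges.tsv"))
  ex <- make_expression(200, 8, 30, seed = seed + 2, dir = dir)
  list(tl = tl, pg = pg, ex = ex)
}

# fixture shaped like the published study: 327-gene compound list,
# 1668-gene disease list, 198-gene overlap carrying the interaction
# network with one planted hub inside a planted 8-clique
make_paper_fixture <- function(dir, seed = 1) {
  tl <- make_target_lists(2000, 327, 1668, 198, seed = seed, dir = dir)
  ov <- gs_intersect(tl$a, tl$b)
  pg <- make_ppi(198, attachment = 2, hub_fraction = 0.3,
                 clique_size = 8, seed = seed + 1, symbols = ov$symbols,
                 path = file.path(dir, "edges.tsv"))
  list(tl = tl, ov = ov, pg = pg)
}
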