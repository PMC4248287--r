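Package: richclub
Title: Topological and Weighted Rich-Club Detection with Randomized Controls
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects rich clubs -- subgroups of prominent nodes that interact
    with one another more than expected by chance -- in weighted undirected
    networks. Implements the topological rich-club coefficient, nine variants
    of maximal weighted connectedness, and the normalized coefficient
    phi_norm = C/C_rand evaluated against degree-preserving (topological),
    strength-preserving weight-decorrelating (weighted), and combined (mixed)
    randomized control ensembles, with empirical permutation p-values along
    the full richness-threshold curve. Includes synthetic generators with
    planted topological or weighted clubs, edge-list input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
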