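Package: paranet
Title: Separating Paralogs from Epaktologs in Sequence Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating paralogous from epaktologous multidomain
    proteins, i.e. proteins related only through independent acquisition of the
    same mobile domain types. Builds directed top-scoring-sequence (TSS)
    similarity networks from all-against-all hit tables and decomposes them
    into strong and weak components; clusters query proteins by shared best
    hit in target proteomes ordered by divergence time; classifies domain
    architecture differences of homolog pairs into positional categories
    (N-terminal, C-terminal, internal, duplication) at multiple e-value
    cutoffs and estimates rates of domain architecture change per million
    years. A forward simulator of multidomain protein family evolution (gene
    duplication, terminal and internal domain gain and loss, tandem domain
    duplication and domain shuffling) provides proteomes with known
    ortholog/paralog/epaktolog structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
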