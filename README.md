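# treedag

Supertree and species-tree estimation by **constrained exact optimization**,
returning *all* optimal trees instead of one.

Combining trees on subsets of a species set S — source trees from published
studies, or gene trees from a phylogenomic dataset — into one tree on S means
optimizing an NP-hard criterion.  A well-established escape is to constrain
the search: collect a set X of allowed bipartitions from complete trees
produced by other methods, and find the exact optimum among trees T with
C(T) ⊆ X by dynamic programming over the allowed clades

    f(c) = max { f(a) + f(b) + w(a, b, S∖c) :  a ⊎ b = c,  a, b allowed },
    f(c) = 0 for |c| = 1,

where w is a tripartition weight whose sum over any rooting of a complete
binary tree equals the whole-tree criterion score F(T).  Both supported
criteria are integer counts —

* **`rfs`** — shared bipartitions with the source trees over their own leaf
  sets (equivalently, minimum total Robinson–Foulds distance);
* **`quartet`** — shared induced 4-taxon topologies with the gene trees (the
  criterion of quartet-based coalescent-aware species-tree estimation)

— so exact ties are common, and on real supertree datasets the number of
co-optimal trees can exceed 10^90.  `treedag` records *every* score-attaining
split of every clade.  The table becomes a DAG representing the full optimal
set, which then supports, exactly and without ever materializing that set:

* counting optima (arbitrary-precision integers),
* the fraction A_c of optimal trees containing each bipartition
  (exact rationals),
* strict / majority / greedy / α-consensus trees,
* uniform sampling and full enumeration of optima,
* branch support corrected for the existence of the other optima
  (raw support × A_c), and a greedy maximum-clade-credibility tree,
* FN / FP / average / F1 error rates against a reference tree.

For whom: anyone building supertrees from incompatible source trees, or
species trees from discordant gene trees, who needs to know whether their
"the" optimal tree is actually one of thousands — and what the stable parts
of the solution set are.

## Worked example

Six taxa, four partially overlapping source trees, three complete constraint
trees that conflict with one another:

```r
library(treedag)
taxa <- taxon_index(letters[1:6])
sources <- lapply(c("((a,b),(c,(e,f)));", "((a,c),(b,(d,f)));",
                    "((a,b),((c,d),f));", "(((a,b),c),(d,e));"), parse_newick)
constraints <- lapply(c("(((a,b),c),((d,e),f));", "(((a,c),b),((d,f),e));",
                        "(((a,b),d),((c,e),f));"), parse_newick)

cs  <- build_constraint_set(constraints, taxa)
src <- source_tree_set(sources, taxa)
dag <- run_dp(enumerate_splits(cs), rfs_scorer(src))
dag
#> solution_dag: rfs criterion on 6 taxa; f(S) = 6
#>   clades: 27  optimal splits: 34
```

Six shared bipartitions is the best any tree drawing its bipartitions from X
can do — and two distinct unrooted trees achieve it (18 rooted optima is
exactly (2n − 3) × 2; the division is checked to be exact):

```r
count_rooted_optima(dag)      #> 18
count_unrooted_optima(dag)    #> 2
bipartition_frequencies(dag)[, 1:3]
#>   bipartition frequency frequency_exact
#> 1     c,d,e,f       1.0        1.000000
#> 2         d,e       0.5        0.500000
#> 3       d,e,f       1.0        1.000000
#> 4         d,f       0.5        0.500000
```

The two optima agree everywhere except whether d pairs with e or with f.
A single "best tree" silently picks one resolution; the strict consensus
keeps exactly the branches present in *every* optimum, and the MCC tree
carries honest support values on the contested branch:

```r
write_newick(extract_one_tree(dag), taxa)        # one optimum, deterministic
#> "(a,b,(c,((d,e),f)));"
write_newick(consensus_tree(dag, "strict"), taxa)
#> "(a,b,(c,(d,e,f)));"
ape::write.tree(mcc_tree(dag))
#> "(a,b,(c,((d,f)0.500000,e)1.000000)1.000000);"

tree_error_rates(consensus_tree(dag, "strict"), constraints[[1]])
#> tree error: FN = 0.3333  FP = 0.0000  avg = 0.1667  F1 = 0.8000  (n = 6)
```

The same pipeline runs from the shell via the installed `exec/treedag`
script: `treedag search --criterion rfs --sources s.nwk --constraint-trees
c.nwk -o best.nwk` (plus `count`, `enumerate`, `sample`, `consensus`,
`annotate`, `mcc`, `score`, `fixture`; `--save-dag`/`--load-dag` reuse one
search across subcommands).

See `vignettes/constrained-optima.Rmd` for the weight decompositions, the
exact-arithmetic design, and what the synthetic validation does and does not
establish.

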