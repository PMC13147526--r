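"""Neutral coalescent haplotype simulation backend.

Usage: python sim_haplotypes.py N_HAPLOTYPES LENGTH_BP NE MU REC SEED OUT

Simulates n haploid genomes from a single panmictic population with
diploid-scaled effective size NE (so expected pairwise diversity is
4*NE*MU per bp), infinite-sites binary mutations, and writes a compact
text panel:

    line 1: "n S L" (counts and region length)
    line 2: S strictly increasing 1-based integer bp positions
    lines 3..n+2: one 0/1 string of length S per haplotype
"""
import sys

import msprime
import numpy as np


def main(argv):
    n, L, Ne, mu, rec, seed, out = argv
    n = int(n)
    L = float(L)
    Ne = float(Ne)
    mu = float(mu)
    rec = float(rec)
    seed = int(seed)
    # ploidy=1 puts msprime on a haploid timescale, so a haploid
    # population of 2*Ne genomes reproduces the diploid scaling
    # theta = 4*Ne*mu used throughout.
    ts = msprime.sim_ancestry(
        samples=n, ploidy=1, population_size=2.0 * Ne,
        sequence_length=L, recombination_rate=rec, random_seed=seed)
    mts = msprime.sim_mutations(
        ts, rate=mu, random_seed=seed + 1,
        model=msprime.BinaryMutationModel(), discrete_genome=False)
    G = mts.genotype_matrix()  # sites x samples, 0/1
    pos = np.array([s.position for s in mts.sites()])
    # polarize to 0/1 and drop anything not segregating
    G = np.minimum(G, 1).astype(np.uint8)
    ac = G.sum(axis=1)
    keep = (ac > 0) & (ac < n)
    G = G[keep]
    pos = pos[keep]
    # integer 1-based, strictly increasing positions (bump collisions)
    p = np.ceil(pos).astype(np.int64)
    p[p < 1] = 1
    if p.size:
        idx = np.arange(p.size, dtype=np.int64)
        p = idx + np.maximum.accumulate(p - idx)
    with open(out, "w") as fh:
        fh.write("%d %d %d\n" % (n, p.size, int(L)))
        fh.write(" ".join(str(v) for v in p))
        fh.write("\n")
        GT = G.T + np.uint8(ord("0"))
        for i in range(n):
            fh.write(GT[i].tobytes().decode("ascii"))
            fh.write("\n")


if __name__ == "__main__":
    main(sys.argv[1:8])
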