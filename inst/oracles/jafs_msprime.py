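"""Independent coalescent oracle: joint AFS under a two-deme IM model.

Calibration matches the package's scaling: time in units of 2*N_A
generations, pairwise coalescence rate 1/nu_i within deme i (haploid
population size nu_i with one generation per scaled unit), per-lineage
backward migration rate M, ancestral deme size 1, and per-locus mutation
rate theta/2 per unit time under infinite sites.

Usage: python jafs_msprime.py n1 n2 nu1 nu2 M tS theta nloci seed
Prints the (n1+1) x (n2+1) joint spectrum of derived-allele counts,
one row per line.
"""
import sys

import msprime
import numpy as np


def main():
    n1, n2 = int(sys.argv[1]), int(sys.argv[2])
    nu1, nu2 = float(sys.argv[3]), float(sys.argv[4])
    M, tS, theta = (float(x) for x in sys.argv[5:8])
    nloci, seed = int(sys.argv[8]), int(sys.argv[9])

    dem = msprime.Demography()
    dem.add_population(name="p1", initial_size=nu1)
    dem.add_population(name="p2", initial_size=nu2)
    dem.add_population(name="anc", initial_size=1.0)
    dem.set_symmetric_migration_rate(["p1", "p2"], M)
    dem.add_population_split(time=tS, derived=["p1", "p2"], ancestral="anc")

    jafs = np.zeros((n1 + 1, n2 + 1))
    rng = np.random.default_rng(seed)
    reps = msprime.sim_ancestry(
        samples={"p1": n1, "p2": n2}, demography=dem, ploidy=1,
        sequence_length=1, num_replicates=nloci, random_seed=seed)
    sets = [list(range(n1)), list(range(n1, n1 + n2))]
    for ts in reps:
        mts = msprime.sim_mutations(
            ts, rate=theta / 2.0, random_seed=int(rng.integers(1, 2**31)),
            model=msprime.BinaryMutationModel(), discrete_genome=False)
        jafs += mts.allele_frequency_spectrum(
            sample_sets=sets, polarised=True, span_normalise=False)
    for row in jafs:
        print(" ".join(str(int(x)) for x in row))


if __name__ == "__main__":
    main()
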