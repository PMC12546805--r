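"""Seeded 2D UMAP embedding of a feature matrix.

Usage: python umap_embed.py IN_CSV OUT_CSV SEED N_NEIGHBORS MIN_DIST
IN_CSV: numeric matrix, no header. OUT_CSV: n x 2 coordinates.
"""
import sys

import numpy as np
import umap


def main():
    in_csv, out_csv, seed, n_neighbors, min_dist = sys.argv[1:6]
    x = np.loadtxt(in_csv, delimiter=",", ndmin=2)
    emb = umap.UMAP(
        n_components=2,
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        random_state=int(seed),
        # spectral initialization needs n >> k; fall back for tiny inputs
        init="random" if x.shape[0] < 20 else "spectral",
    ).fit_transform(x)
    np.savetxt(out_csv, emb, delimiter=",")


if __name__ == "__main__":
    main()
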