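"""Run UMAP on a numeric CSV and write the embedding as CSV.

Usage: python run_umap.py IN_CSV OUT_CSV N_NEIGHBOURS MIN_DIST N_COMPONENTS SEED
Single-threaded and seeded so repeated runs on the same input are identical.
"""
import sys

import numpy as np
import pandas as pd
import umap


def main(argv):
    in_csv, out_csv = argv[1], argv[2]
    n_neighbours = int(argv[3])
    min_dist = float(argv[4])
    n_components = int(argv[5])
    seed = int(argv[6])

    x = pd.read_csv(in_csv).to_numpy(dtype=np.float64)
    reducer = umap.UMAP(
        n_neighbors=n_neighbours,
        min_dist=min_dist,
        n_components=n_components,
        random_state=seed,
        n_jobs=1,
        init="spectral",
    )
    coords = reducer.fit_transform(x)
    pd.DataFrame(coords).to_csv(out_csv, index=False, header=False)


if __name__ == "__main__":
    main(sys.argv)
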