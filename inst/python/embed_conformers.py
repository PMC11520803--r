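"""Deterministic conformer embedding helper.

Reads a TSV of ``id<TAB>smiles`` lines from the file given as argv[1],
embeds up to ``--nconf`` conformers per molecule with the ETKDG
distance-geometry method at a fixed random seed, and writes one line per
heavy atom per conformer to stdout:

    id<TAB>conformer<TAB>atom<TAB>element<TAB>charge<TAB>aromatic<TAB>x<TAB>y<TAB>z

Molecules that fail 3D embedding emit a single line ``id<TAB>FAIL``.
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main() -> None:
    path = sys.argv[1]
    seed = int(sys.argv[2]) if len(sys.argv) > 2 else 1102
    nconf = int(sys.argv[3]) if len(sys.argv) > 3 else 3
    out = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            mid, smi = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.append(f"{mid}\tFAIL")
                continue
            molh = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            # collapse near-duplicate geometries so rigid molecules yield
            # a single conformer
            params.pruneRmsThresh = 0.35
            conf_ids = AllChem.EmbedMultipleConfs(molh, numConfs=nconf,
                                                  params=params)
            if len(conf_ids) == 0:
                out.append(f"{mid}\tFAIL")
                continue
            molnoh = Chem.RemoveHs(molh)
            for ci, cid in enumerate(conf_ids):
                conf = molnoh.GetConformer(cid)
                for ai, atom in enumerate(molnoh.GetAtoms()):
                    pos = conf.GetAtomPosition(ai)
                    out.append(
                        f"{mid}\t{ci}\t{ai}\t{atom.GetSymbol()}\t"
                        f"{atom.GetFormalCharge()}\t"
                        f"{int(atom.GetIsAromatic())}\t"
                        f"{pos.x:.6f}\t{pos.y:.6f}\t{pos.z:.6f}")
    sys.stdout.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main()
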