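"""Batch SMILES featurizer for the cypdfi R package.

Reads a JSON file (list of SMILES strings) given as argv[1], writes a JSON
list of per-compound featurization records to argv[2].  Each record:

  ok               bool
  error            str (only when ok is false)
  canonical        canonical SMILES of the (largest organic fragment of the) input
  fragment_reduced bool, true when a multi-fragment input was reduced
  n_atoms          heavy-atom count
  bits             sorted on-bit indices of the 1024-bit radius-2 Morgan fingerprint
  bit_envs         {bit: [[center_atom, radius], ...]} (0-based atoms)
  atoms            per-atom 9-channel integer codes (0-based vocabulary indices)
  bonds            per-bond [begin, end, type_code, stereo_code, conj_code]

Vocabularies follow the common open-graph-benchmark encoding so that codes are
stable across package versions (see VOCAB below).
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem import rdFingerprintGenerator
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

VOCAB_VERSION = "cypdfi-vocab-1"

ATOMIC_NUMS = list(range(1, 101))            # + misc
CHIRALITY = ["CHI_UNSPECIFIED", "CHI_TETRAHEDRAL_CW", "CHI_TETRAHEDRAL_CCW"]  # + misc
DEGREES = list(range(0, 11))                 # + misc
CHARGES = list(range(-5, 6))                 # + misc
NUM_HS = list(range(0, 9))                   # + misc
RADICALS = list(range(0, 5))                 # + misc
HYBRID = ["SP", "SP2", "SP3", "SP3D", "SP3D2"]  # + misc
BOND_TYPES = ["SINGLE", "DOUBLE", "TRIPLE", "AROMATIC"]  # + misc
STEREO = ["STEREONONE", "STEREOZ", "STEREOE", "STEREOCIS", "STEREOTRANS", "STEREOANY"]

VOCAB_SIZES = {
    "atomic_num": len(ATOMIC_NUMS) + 1,
    "chirality": len(CHIRALITY) + 1,
    "degree": len(DEGREES) + 1,
    "formal_charge": len(CHARGES) + 1,
    "num_hs": len(NUM_HS) + 1,
    "radical_electrons": len(RADICALS) + 1,
    "hybridization": len(HYBRID) + 1,
    "aromatic": 2,
    "in_ring": 2,
    "bond_type": len(BOND_TYPES) + 1,
    "bond_stereo": len(STEREO) + 1,
    "conjugated": 2,
}


def code(value, table):
    try:
        return table.index(value)
    except ValueError:
        return len(table)  # misc bucket


def atom_codes(atom):
    return [
        code(atom.GetAtomicNum(), ATOMIC_NUMS),
        code(str(atom.GetChiralTag()), CHIRALITY),
        code(atom.GetTotalDegree(), DEGREES),
        code(atom.GetFormalCharge(), CHARGES),
        code(atom.GetTotalNumHs(), NUM_HS),
        code(atom.GetNumRadicalElectrons(), RADICALS),
        code(str(atom.GetHybridization()), HYBRID),
        int(atom.GetIsAromatic()),
        int(atom.IsInRing()),
    ]


def bond_codes(bond):
    return [
        code(str(bond.GetBondType()), BOND_TYPES),
        code(str(bond.GetStereo()), STEREO),
        int(bond.GetIsConjugated()),
    ]


_chooser = rdMolStandardize.LargestFragmentChooser(preferOrganic=True)
_fpgen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=1024)


def featurize(smiles):
    if not isinstance(smiles, str) or smiles.strip() == "":
        return {"ok": False, "error": "empty SMILES"}
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    fragment_reduced = False
    if len(Chem.GetMolFrags(mol)) > 1:
        mol = _chooser.choose(mol)
        fragment_reduced = True
    if mol is None or mol.GetNumHeavyAtoms() == 0:
        return {"ok": False, "error": "no heavy atoms after fragment selection"}
    canonical = Chem.MolToSmiles(mol)
    ao = rdFingerprintGenerator.AdditionalOutput()
    ao.AllocateBitInfoMap()
    fp = _fpgen.GetFingerprint(mol, additionalOutput=ao)
    bit_envs = {str(b): [list(env) for env in envs]
                for b, envs in ao.GetBitInfoMap().items()}
    atoms = [atom_codes(a) for a in mol.GetAtoms()]
    bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx()] + bond_codes(b)
             for b in mol.GetBonds()]
    return {
        "ok": True,
        "canonical": canonical,
        "fragment_reduced": fragment_reduced,
        "n_atoms": mol.GetNumHeavyAtoms(),
        "bits": sorted(fp.GetOnBits()),
        "bit_envs": bit_envs,
        "atoms": atoms,
        "bonds": bonds,
    }


def main():
    with open(sys.argv[1]) as fh:
        smiles_list = json.load(fh)
    out = {
        "vocab_version": VOCAB_VERSION,
        "vocab_sizes": VOCAB_SIZES,
        "records": [featurize(s) for s in smiles_list],
    }
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
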