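"""RDKit helper used by the molmpnn R package.

Reads one JSON request on stdin, writes one JSON response on stdout.

Request:  {"op": "perceive" | "charge_parent" | "scaffold",
           "smiles": ["...", ...]}
Response: {"results": [<one object per input SMILES>]}

Every per-molecule object carries "ok": true/false so that R can handle
parse failures without the whole batch dying.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

BOND_CLASSES = {
    Chem.BondType.SINGLE: 1,
    Chem.BondType.DOUBLE: 2,
    Chem.BondType.TRIPLE: 3,
    Chem.BondType.AROMATIC: 4,
}

HYBRIDIZATIONS = {
    Chem.HybridizationType.SP: 1,
    Chem.HybridizationType.SP2: 2,
    Chem.HybridizationType.SP3: 3,
    Chem.HybridizationType.SP3D: 4,
    Chem.HybridizationType.SP3D2: 5,
}


def perceive(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    atoms = []
    for a in mol.GetAtoms():
        atoms.append(
            {
                "symbol": a.GetSymbol(),
                "degree": a.GetDegree(),
                "implicit_valence": a.GetImplicitValence(),
                "formal_charge": a.GetFormalCharge(),
                "radical_electrons": a.GetNumRadicalElectrons(),
                "hybridization": HYBRIDIZATIONS.get(a.GetHybridization(), 0),
                "aromatic": bool(a.GetIsAromatic()),
                "total_num_h": a.GetTotalNumHs(),
            }
        )
    bonds = []
    for b in mol.GetBonds():
        cls = BOND_CLASSES.get(b.GetBondType())
        if cls is None:
            return {
                "ok": False,
                "error": "bond type outside {single, double, triple, aromatic}: %s"
                % b.GetBondType(),
            }
        bonds.append(
            {
                "a1": b.GetBeginAtomIdx(),
                "a2": b.GetEndAtomIdx(),
                "bond_class": cls,
            }
        )
    return {
        "ok": True,
        "n_atoms": mol.GetNumAtoms(),
        "atoms": atoms,
        "bonds": bonds,
        "canonical_smiles": Chem.MolToSmiles(mol),
    }


def charge_parent(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    try:
        parent = rdMolStandardize.ChargeParent(mol)
    except Exception as exc:  # standardizer failure -> row is droppable in R
        return {"ok": False, "error": "standardization failed: %s" % exc}
    if parent is None or parent.GetNumAtoms() == 0:
        return {"ok": False, "error": "no organic covalent unit"}
    residual = Chem.GetFormalCharge(parent)
    return {
        "ok": True,
        "smiles": Chem.MolToSmiles(parent),
        "residual_charge": residual,
    }


def scaffold(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    scaf = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
    return {"ok": True, "scaffold": scaf}


OPS = {"perceive": perceive, "charge_parent": charge_parent, "scaffold": scaffold}


def main():
    req = json.load(sys.stdin)
    op = req["op"]
    if op not in OPS:
        raise SystemExit("unknown op: %s" % op)
    fn = OPS[op]
    results = [fn(s) for s in req["smiles"]]
    json.dump({"results": results}, sys.stdout)


if __name__ == "__main__":
    main()
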