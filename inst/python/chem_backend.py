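#!/usr/bin/env python
"""Chemistry backend for the molattn R package.

Thin batch wrapper around RDKit: parses SMILES, computes per-atom properties,
embeds one 3D conformer, matches SMARTS patterns and produces 2D depiction
coordinates. All I/O is tab-separated text so the R side needs no bindings.

Subcommands
  describe --smiles FILE --outdir DIR --seed INT [--coords {3d,none}]
  match    --smiles FILE --smarts FILE --outdir DIR
  depict   --smiles FILE --outdir DIR
  sdf2smi  --sdf FILE --out FILE
"""

import argparse
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

HYB_NAMES = {
    Chem.HybridizationType.S: "S",
    Chem.HybridizationType.SP: "SP",
    Chem.HybridizationType.SP2: "SP2",
    Chem.HybridizationType.SP3: "SP3",
    Chem.HybridizationType.SP3D: "SP3D",
    Chem.HybridizationType.SP3D2: "SP3D2",
    Chem.HybridizationType.UNSPECIFIED: "unspecified",
}

CHI_NAMES = {
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "CW",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "CCW",
    Chem.ChiralType.CHI_UNSPECIFIED: "unspecified",
}


def read_smiles(path):
    """Input: idx<TAB>smiles, no header."""
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            idx, smi = line.split("\t", 1)
            rows.append((idx, smi))
    return rows


def parse_mol(smi):
    return Chem.MolFromSmiles(smi)


def embed_coords(mol, seed):
    """One conformer, default embedding parameters, fixed seed.

    Returns heavy-atom coordinate list or None on failure.
    """
    molh = Chem.AddHs(mol)
    conf_id = AllChem.EmbedMolecule(molh, randomSeed=seed)
    if conf_id < 0:
        return None
    conf = molh.GetConformer(conf_id)
    n = mol.GetNumAtoms()  # AddHs appends hydrogens after the heavy atoms
    return [conf.GetAtomPosition(i) for i in range(n)]


def cmd_describe(args):
    rows = read_smiles(args.smiles)
    mols_out = open(os.path.join(args.outdir, "mols.tsv"), "w")
    atoms_out = open(os.path.join(args.outdir, "atoms.tsv"), "w")
    bonds_out = open(os.path.join(args.outdir, "bonds.tsv"), "w")
    mols_out.write("idx\tstatus\tn_atoms\tcanonical_smiles\n")
    atoms_out.write("idx\tatom\tsymbol\tn_heavy\tn_h\taromatic\tin_ring\t"
                    "hybridization\tchirality\tformal_charge\t"
                    "explicit_valence\timplicit_valence\tx\ty\tz\n")
    bonds_out.write("idx\ta1\ta2\taromatic\torder\n")
    want3d = args.coords == "3d"
    for idx, smi in rows:
        mol = parse_mol(smi)
        if mol is None:
            mols_out.write(f"{idx}\tparse_error\t0\t\n")
            continue
        coords = None
        if want3d:
            coords = embed_coords(mol, args.seed)
            if coords is None:
                mols_out.write(f"{idx}\tembed_error\t{mol.GetNumAtoms()}\t"
                               f"{Chem.MolToSmiles(mol)}\n")
                continue
        mols_out.write(f"{idx}\tok\t{mol.GetNumAtoms()}\t{Chem.MolToSmiles(mol)}\n")
        for atom in mol.GetAtoms():
            i = atom.GetIdx()
            nheavy = sum(1 for nb in atom.GetNeighbors()
                         if nb.GetAtomicNum() > 1)
            hyb = HYB_NAMES.get(atom.GetHybridization(), "other")
            chi = CHI_NAMES.get(atom.GetChiralTag(), "other")
            if coords is not None:
                x, y, z = coords[i].x, coords[i].y, coords[i].z
            else:
                x = y = z = 0.0
            atoms_out.write(
                f"{idx}\t{i}\t{atom.GetSymbol()}\t{nheavy}\t"
                f"{atom.GetTotalNumHs()}\t{int(atom.GetIsAromatic())}\t"
                f"{int(atom.IsInRing())}\t{hyb}\t{chi}\t"
                f"{atom.GetFormalCharge()}\t{atom.GetExplicitValence()}\t"
                f"{atom.GetImplicitValence()}\t"
                f"{x:.6f}\t{y:.6f}\t{z:.6f}\n")
        for bond in mol.GetBonds():
            bonds_out.write(f"{idx}\t{bond.GetBeginAtomIdx()}\t"
                            f"{bond.GetEndAtomIdx()}\t"
                            f"{int(bond.GetIsAromatic())}\t"
                            f"{bond.GetBondTypeAsDouble():g}\n")
    for fh in (mols_out, atoms_out, bonds_out):
        fh.close()


def cmd_match(args):
    rows = read_smiles(args.smiles)
    patterns = []
    with open(args.smarts) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            pidx, sma = line.split("\t", 1)
            patt = Chem.MolFromSmarts(sma)
            if patt is None:
                sys.stderr.write(f"bad SMARTS [{pidx}]: {sma}\n")
                sys.exit(2)
            patterns.append((pidx, patt))
    m_out = open(os.path.join(args.outdir, "matches.tsv"), "w")
    a_out = open(os.path.join(args.outdir, "match_atoms.tsv"), "w")
    m_out.write("idx\tpattern\tn_matches\n")
    a_out.write("idx\tpattern\tatom\n")
    for idx, smi in rows:
        mol = parse_mol(smi)
        if mol is None:
            for pidx, _ in patterns:
                m_out.write(f"{idx}\t{pidx}\tNA\n")
            continue
        for pidx, patt in patterns:
            hits = mol.GetSubstructMatches(patt)
            m_out.write(f"{idx}\t{pidx}\t{len(hits)}\n")
            atoms = sorted({a for hit in hits for a in hit})
            for a in atoms:
                a_out.write(f"{idx}\t{pidx}\t{a}\n")
    m_out.close()
    a_out.close()


def cmd_depict(args):
    rows = read_smiles(args.smiles)
    out = open(os.path.join(args.outdir, "coords2d.tsv"), "w")
    out.write("idx\tatom\tsymbol\tx\ty\n")
    bout = open(os.path.join(args.outdir, "bonds2d.tsv"), "w")
    bout.write("idx\ta1\ta2\torder\n")
    for idx, smi in rows:
        mol = parse_mol(smi)
        if mol is None:
            continue
        AllChem.Compute2DCoords(mol)
        conf = mol.GetConformer()
        for atom in mol.GetAtoms():
            p = conf.GetAtomPosition(atom.GetIdx())
            out.write(f"{idx}\t{atom.GetIdx()}\t{atom.GetSymbol()}\t"
                      f"{p.x:.4f}\t{p.y:.4f}\n")
        for bond in mol.GetBonds():
            bout.write(f"{idx}\t{bond.GetBeginAtomIdx()}\t"
                       f"{bond.GetEndAtomIdx()}\t"
                       f"{bond.GetBondTypeAsDouble():g}\n")
    out.close()
    bout.close()


def cmd_sdf2smi(args):
    suppl = Chem.SDMolSupplier(args.sdf, sanitize=True)
    with open(args.out, "w") as out:
        out.write("id\tsmiles\n")
        for k, mol in enumerate(suppl):
            if mol is None:
                out.write(f"sdf_{k}\t\n")
                continue
            name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
            out.write(f"{name or 'sdf_' + str(k)}\t{Chem.MolToSmiles(mol)}\n")


def main():
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="cmd", required=True)

    d = sub.add_parser("describe")
    d.add_argument("--smiles", required=True)
    d.add_argument("--outdir", required=True)
    d.add_argument("--seed", type=int, default=42)
    d.add_argument("--coords", choices=["3d", "none"], default="3d")
    d.set_defaults(func=cmd_describe)

    m = sub.add_parser("match")
    m.add_argument("--smiles", required=True)
    m.add_argument("--smarts", required=True)
    m.add_argument("--outdir", required=True)
    m.set_defaults(func=cmd_match)

    p = sub.add_parser("depict")
    p.add_argument("--smiles", required=True)
    p.add_argument("--outdir", required=True)
    p.set_defaults(func=cmd_depict)

    s = sub.add_parser("sdf2smi")
    s.add_argument("--sdf", required=True)
    s.add_argument("--out", required=True)
    s.set_defaults(func=cmd_sdf2smi)

    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
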