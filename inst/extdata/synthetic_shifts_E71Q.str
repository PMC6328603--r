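data_synthetic_e71q

# SYNTHETIC chemical-shift table: generated stand-in fixture, not a
# BMRB deposition. Encodes the published variant-minus-WT chemical
# shift differences for channel variant E71Q on an invented
# wild-type baseline.

save_assigned_chem_shift_list_E71Q
   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts
   _Assigned_chem_shift_list.ID            1

   loop_
      _Atom_chem_shift.ID
      _Atom_chem_shift.Seq_ID
      _Atom_chem_shift.Comp_ID
      _Atom_chem_shift.Atom_ID
      _Atom_chem_shift.Atom_type
      _Atom_chem_shift.Val
      _Atom_chem_shift.Val_err

        1   60 VAL  H    H     7.991 0.05
        2   60 VAL  N    N   115.448 0.05
        3   60 VAL  C    C   175.013 0.05
        4   60 VAL  CA   C    56.014 0.05
        5   61 THR  H    H     8.690 0.05
        6   61 THR  N    N   126.127 0.05
        7   61 THR  C    C   177.625 0.05
        8   61 THR  CA   C    57.513 0.05
        9   62 ALA  H    H     8.105 0.05
       10   62 ALA  N    N   123.389 0.05
       11   62 ALA  C    C   175.682 0.05
       12   62 ALA  CA   C    58.973 0.05
       13   63 THR  H    H     8.801 0.05
       14   63 THR  N    N   120.022 0.05
       15   63 THR  C    C   173.513 0.05
       16   63 THR  CA   C    54.964 0.05
       17   64 ARG  H    H     8.179 0.05
       18   64 ARG  N    N   117.352 0.05
       19   64 ARG  C    C   176.107 0.05
       20   64 ARG  CA   C    56.428 0.05
       21   65 ALA  H    H     7.617 0.05
       22   65 ALA  N    N   114.591 0.05
       23   65 ALA  C    C   174.225 0.05
       24   65 ALA  CA   C    57.979 0.05
       25   66 LEU  H    H     8.318 0.05
       26   66 LEU  N    N   125.171 0.05
       27   66 LEU  C    C   176.544 0.05
       28   66 LEU  CA   C    53.988 0.05
       29   67 TRP  H    H     7.560 0.05
       30   67 TRP  N    N   121.600 0.05
       31   67 TRP  C    C   174.502 0.05
       32   67 TRP  CA   C    55.517 0.05
       33   67 TRP  NE1  N   129.413 0.05
       34   67 TRP  HE1  H    10.147 0.05
       35   68 TRP  H    H     8.420 0.05
       36   68 TRP  N    N   119.090 0.05
       37   68 TRP  C    C   177.235 0.05
       38   68 TRP  CA   C    57.020 0.05
       39   68 TRP  NE1  N   129.410 0.05
       40   68 TRP  HE1  H    10.162 0.05
       41   69 SER  H    H     7.821 0.05
       42   69 SER  N    N   116.336 0.05
       43   69 SER  C    C   175.021 0.05
       44   69 SER  CA   C    58.465 0.05
       45   70 VAL  H    H     8.506 0.05
       46   70 VAL  N    N   113.034 0.05
       47   70 VAL  C    C   177.607 0.05
       48   70 VAL  CA   C    54.541 0.05
       49   71 GLN  H    H     7.893 0.05
       50   71 GLN  N    N   124.282 0.05
       51   71 GLN  C    C   175.752 0.05
       52   71 GLN  CA   C    56.077 0.05
       53   72 THR  H    H     8.624 0.05
       54   72 THR  N    N   121.609 0.05
       55   72 THR  C    C   173.551 0.05
       56   72 THR  CA   C    57.416 0.05
       57   73 ALA  H    H     8.023 0.05
       58   73 ALA  N    N   118.222 0.05
       59   73 ALA  C    C   176.087 0.05
       60   73 ALA  CA   C    59.040 0.05
       61   74 THR  H    H     8.697 0.05
       62   74 THR  N    N   115.460 0.05
       63   74 THR  C    C   174.175 0.05
       64   74 THR  CA   C    55.045 0.05
       65   75 THR  H    H     8.116 0.05
       66   75 THR  N    N   126.069 0.05
       67   75 THR  C    C   176.500 0.05
       68   75 THR  CA   C    56.533 0.05
       69   76 VAL  H    H     8.801 0.05
       70   76 VAL  N    N   123.373 0.05
       71   76 VAL  C    C   174.050 0.05
       72   76 VAL  CA   C    57.992 0.05
       73   77 GLY  H    H     8.194 0.05
       74   77 GLY  N    N   120.015 0.05
       75   77 GLY  C    C   177.192 0.05
       76   77 GLY  CA   C    44.892 0.05
       77   78 TYR  H    H     7.710 0.05
       78   78 TYR  N    N   118.000 0.05
       79   78 TYR  C    C   175.011 0.05
       80   78 TYR  CA   C    55.300 0.05
       81   79 GLY  H    H     8.317 0.05
       82   79 GLY  N    N   114.579 0.05
       83   79 GLY  C    C   177.616 0.05
       84   79 GLY  CA   C    45.086 0.05
       85   80 ASP  H    H     7.600 0.05
       86   80 ASP  N    N   124.600 0.05
       87   80 ASP  C    C   175.622 0.05
       88   80 ASP  CA   C    58.471 0.05
       89   81 LEU  H    H     8.392 0.05
       90   81 LEU  N    N   122.522 0.05
       91   81 LEU  C    C   173.505 0.05
       92   81 LEU  CA   C    54.459 0.05
       93   82 TYR  H    H     7.801 0.05
       94   82 TYR  N    N   119.107 0.05
       95   82 TYR  C    C   176.056 0.05
       96   82 TYR  CA   C    55.996 0.05
       97   83 PRO  N    N   116.459 0.05
       98   83 PRO  C    C   174.231 0.05
       99   83 PRO  CA   C    57.512 0.05
      100   84 VAL  H    H     7.900 0.05
      101   84 VAL  N    N   112.935 0.05
      102   84 VAL  C    C   176.562 0.05
      103   84 VAL  CA   C    59.013 0.05
      104   85 THR  H    H     8.610 0.05
      105   85 THR  N    N   124.259 0.05
      106   85 THR  C    C   174.563 0.05
      107   85 THR  CA   C    54.999 0.05
      108   86 LEU  H    H     8.001 0.05
      109   86 LEU  N    N   121.598 0.05
      110   86 LEU  C    C   177.281 0.05
      111   86 LEU  CA   C    56.459 0.05
      112   87 TRP  H    H     8.719 0.05
      113   87 TRP  N    N   118.254 0.05
      114   87 TRP  C    C   174.947 0.05
      115   87 TRP  CA   C    57.999 0.05
      116   87 TRP  NE1  N   129.411 0.05
      117   87 TRP  HE1  H    10.153 0.05

   stop_

save_
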