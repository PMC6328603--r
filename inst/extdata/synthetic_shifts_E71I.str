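data_synthetic_e71i

# SYNTHETIC chemical-shift table: generated stand-in fixture, not a
# BMRB deposition. Encodes the published variant-minus-WT chemical
# shift differences for channel variant E71I on an invented
# wild-type baseline.

save_assigned_chem_shift_list_E71I
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

        1   60 VAL  H    H     7.988 0.05
        2   60 VAL  N    N   115.544 0.05
        3   60 VAL  C    C   174.962 0.05
        4   60 VAL  CA   C    55.965 0.05
        5   61 THR  H    H     8.731 0.05
        6   61 THR  N    N   126.039 0.05
        7   61 THR  C    C   177.654 0.05
        8   61 THR  CA   C    57.579 0.05
        9   62 ALA  H    H     8.070 0.05
       10   62 ALA  N    N   123.427 0.05
       11   62 ALA  C    C   175.757 0.05
       12   62 ALA  CA   C    58.995 0.05
       13   63 THR  H    H     8.798 0.05
       14   63 THR  N    N   119.913 0.05
       15   63 THR  C    C   173.565 0.05
       16   63 THR  CA   C    55.000 0.05
       17   64 ARG  H    H     8.207 0.05
       18   64 ARG  N    N   117.324 0.05
       19   64 ARG  C    C   176.132 0.05
       20   64 ARG  CA   C    56.538 0.05
       21   65 ALA  H    H     7.612 0.05
       22   65 ALA  N    N   114.555 0.05
       23   65 ALA  C    C   174.226 0.05
       24   65 ALA  CA   C    58.018 0.05
       25   66 LEU  H    H     8.288 0.05
       26   66 LEU  N    N   125.216 0.05
       27   66 LEU  C    C   176.471 0.05
       28   66 LEU  CA   C    53.952 0.05
       29   67 TRP  H    H     8.060 0.05
       30   67 TRP  N    N   124.800 0.05
       31   67 TRP  C    C   174.618 0.05
       32   67 TRP  CA   C    55.500 0.05
       33   67 TRP  NE1  N   129.427 0.05
       34   67 TRP  HE1  H    10.134 0.05
       35   68 TRP  H    H     8.399 0.05
       36   68 TRP  N    N   119.163 0.05
       37   68 TRP  C    C   177.151 0.05
       38   68 TRP  CA   C    56.999 0.05
       39   68 TRP  NE1  N   129.437 0.05
       40   68 TRP  HE1  H    10.150 0.05
       41   69 SER  H    H     7.812 0.05
       42   69 SER  N    N   116.470 0.05
       43   69 SER  C    C   174.938 0.05
       44   69 SER  CA   C    58.427 0.05
       45   70 VAL  H    H     8.720 0.05
       46   70 VAL  N    N   114.400 0.05
       47   70 VAL  C    C   177.623 0.05
       48   70 VAL  CA   C    54.479 0.05
       49   71 ILE  H    H     7.928 0.05
       50   71 ILE  N    N   124.323 0.05
       51   71 ILE  C    C   175.648 0.05
       52   71 ILE  CA   C    56.004 0.05
       53   72 THR  H    H     8.598 0.05
       54   72 THR  N    N   121.615 0.05
       55   72 THR  C    C   173.524 0.05
       56   72 THR  CA   C    57.557 0.05
       57   73 ALA  H    H     8.018 0.05
       58   73 ALA  N    N   118.256 0.05
       59   73 ALA  C    C   176.111 0.05
       60   73 ALA  CA   C    58.971 0.05
       61   74 THR  H    H     8.694 0.05
       62   74 THR  N    N   115.488 0.05
       63   74 THR  C    C   174.184 0.05
       64   74 THR  CA   C    55.900 0.05
       65   75 THR  H    H     8.118 0.05
       66   75 THR  N    N   126.061 0.05
       67   75 THR  C    C   176.568 0.05
       68   75 THR  CA   C    56.505 0.05
       69   76 VAL  H    H     8.811 0.05
       70   76 VAL  N    N   123.396 0.05
       71   76 VAL  C    C   175.370 0.05
       72   76 VAL  CA   C    57.987 0.05
       73   77 GLY  H    H     8.248 0.05
       74   77 GLY  N    N   120.023 0.05
       75   77 GLY  C    C   177.216 0.05
       76   77 GLY  CA   C    44.925 0.05
       77   78 TYR  H    H     7.180 0.05
       78   78 TYR  N    N   114.800 0.05
       79   78 TYR  C    C   174.962 0.05
       80   78 TYR  CA   C    53.560 0.05
       81   79 GLY  H    H     8.292 0.05
       82   79 GLY  N    N   114.571 0.05
       83   79 GLY  C    C   177.603 0.05
       84   79 GLY  CA   C    45.096 0.05
       85   80 ASP  H    H     8.100 0.05
       86   80 ASP  N    N   127.800 0.05
       87   80 ASP  C    C   175.726 0.05
       88   80 ASP  CA   C    58.486 0.05
       89   81 LEU  H    H     8.393 0.05
       90   81 LEU  N    N   122.449 0.05
       91   81 LEU  C    C   173.514 0.05
       92   81 LEU  CA   C    54.520 0.05
       93   82 TYR  H    H     7.781 0.05
       94   82 TYR  N    N   119.143 0.05
       95   82 TYR  C    C   176.113 0.05
       96   82 TYR  CA   C    55.964 0.05
       97   83 PRO  N    N   116.454 0.05
       98   83 PRO  C    C   174.191 0.05
       99   83 PRO  CA   C    57.526 0.05
      100   84 VAL  H    H     7.916 0.05
      101   84 VAL  N    N   113.055 0.05
      102   84 VAL  C    C   176.504 0.05
      103   84 VAL  CA   C    58.962 0.05
      104   85 THR  H    H     8.594 0.05
      105   85 THR  N    N   124.248 0.05
      106   85 THR  C    C   174.611 0.05
      107   85 THR  CA   C    55.025 0.05
      108   86 LEU  H    H     8.012 0.05
      109   86 LEU  N    N   121.635 0.05
      110   86 LEU  C    C   177.194 0.05
      111   86 LEU  CA   C    56.500 0.05
      112   87 TRP  H    H     8.703 0.05
      113   87 TRP  N    N   118.189 0.05
      114   87 TRP  C    C   174.925 0.05
      115   87 TRP  CA   C    58.012 0.05
      116   87 TRP  NE1  N   129.403 0.05
      117   87 TRP  HE1  H    10.139 0.05

   stop_

save_
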