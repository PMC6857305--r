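channel	RS1	RS2	RS3	RS4	RS5	RS6
clustered:del:1-10kb	0.004717	0.004717	0.004717	0.109375	0.004505	0.005495
clustered:del:10-100kb	0.004717	0.004717	0.004717	0.005208	0.004505	0.17033
clustered:del:100kb-1Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:del:1-10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:del:>10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:dup:1-10kb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:dup:10-100kb	0.004717	0.004717	0.004717	0.005208	0.004505	0.115385
clustered:dup:100kb-1Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:dup:1-10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:dup:>10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:inv:1-10kb	0.004717	0.004717	0.004717	0.109375	0.004505	0.28022
clustered:inv:10-100kb	0.004717	0.004717	0.004717	0.005208	0.004505	0.28022
clustered:inv:100kb-1Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:inv:1-10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:inv:>10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
clustered:trans	0.004717	0.004717	0.004717	0.630208	0.004505	0.005495
non-clustered:del:1-10kb	0.004717	0.004717	0.004717	0.005208	0.454955	0.005495
non-clustered:del:10-100kb	0.004717	0.004717	0.004717	0.005208	0.31982	0.005495
non-clustered:del:100kb-1Mb	0.004717	0.193396	0.004717	0.005208	0.094595	0.005495
non-clustered:del:1-10Mb	0.004717	0.193396	0.004717	0.005208	0.004505	0.005495
non-clustered:del:>10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:dup:1-10kb	0.004717	0.004717	0.476415	0.005208	0.004505	0.005495
non-clustered:dup:10-100kb	0.004717	0.004717	0.382075	0.005208	0.004505	0.005495
non-clustered:dup:100kb-1Mb	0.382075	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:dup:1-10Mb	0.382075	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:dup:>10Mb	0.099057	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:inv:1-10kb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:inv:10-100kb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:inv:100kb-1Mb	0.004717	0.146226	0.004717	0.005208	0.004505	0.005495
non-clustered:inv:1-10Mb	0.004717	0.146226	0.004717	0.005208	0.004505	0.005495
non-clustered:inv:>10Mb	0.004717	0.004717	0.004717	0.005208	0.004505	0.005495
non-clustered:trans	0.004717	0.193396	0.004717	0.005208	0.004505	0.005495
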