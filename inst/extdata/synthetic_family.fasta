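>A
RHDCKQNHQMRTGPCERNNLWFPNISLRIGQGRVRTCWCVTSKGWQATESSEFETLVSFY
NDYLQNLKTAQGWVLNFQMTGHQFMRSWHVRSIGYKVIQDQDMNHAAETDKWDLNCSWGH
IWNDNTILYHEIWPDCCMEMCSCPGMDLNKLEKLHKSVISKSEYHQATKLTKYDGHKCHP
QYLWTRFDLDMVCCFTLGAADDEEQVHPGHQGCTHKRELFEWWPCYCNRYHVNYNDNFKE
LKIRHRQQMKSDICGIPKMRDLEEVHCHRWQTCPYEAQDAHEACQPNQFKHFFDITRFLF
DVEPLPFGIHERGDSGLVRQYGTKCMKWVNSLQAQCGVWTNCQWDDGWEDRTAHHP
>B
RHDCKQNHQMRTGPQEFNNLWFPNISLRIGQGRVRTCWCVTSKGWQATESSEFETLVSFY
NDYLQNLKTAQGWVLFFQMTGHQFMRSWHVRSIGYKVIQDQDMNHAAETDKWDLNCSWGH
IWNDNTILYHEIWPDICMEMCSCPGMDLNKLEKLHKSVISKSEYHQATKLTKYDGHKCHP
QYLWTRFMLDMVCCFTLGAADDEEQVDPGHQGCTHKRELFEWWPCLCNRYHVNYNDNFKE
LKIRHRQQMKSDICGIPKGRDLEEVHCHRWQTCPYEAQDAHEACQPNQFKHFFDITRFLF
DVEPLPFGIHERGDSGLVRQYGTKCMKWVNSLQAQCGVWTNCQWDDGWEDRSAHHP
>C
RSTCKQNLQMRTGPQEFNNLNKPCISLRIGQGQVRTCWCVTSYGWQATESDEFETLVSFY
NDYLQNLKTAQSWALNFQVTDHQFWYSWHLRSIGYKVIQDQDMNHFASTDKWDLHCSWGH
IWNDNTILYHEIWPPICMEMCSCPGMDLMKHEKMHKSVISKSEYHQLTKHTKYDYHKCHP
QYLWTRFRLWMVCCFTLGAAADCEQVWPGHNGCVHKRGLFEWWPMYLNVSHVNYKDNFKE
GLIRHRDSISSYICGIPKMRDLEWVHCHRAQEKPYLAQDAHEACQPNNLKHHFDITRFLA
DVEPLPRGIHERGDSGYVPQPGTKCMKWVNSLQAQCGVWTNCQWDDPWEDRSWHHP
>D
RSTCKQNLQMRTGPQEFNNLNKPCISLRIGQGQVRTCWCVTSYGWQATESDEFETLVSFY
NDYLQNLKTAQSWALNFQMTDHQFMYSWHLRSMGYKVIQDQDMNHFASTDKWDLHCSVGH
IWNDNTILYHEIWPPICMEMCSCPGMDLMKWMKMHKSVISKSEYHQLTKHTKYDYHKCHP
QYLWTRFRLWMVCCFTLGAAADCEQVWPGHNGCVHKRGDFEWWPMYLNVSHVNYKDNFKE
GKIRHRDSISSYICGIPKMRDLEWVHCHRAQEKPYLAQDAHEACQPNNLKHHFDITRFLA
DVEPLPRGIHERGDSGYVPQPGTKCMKWSNSLQAQCGVWTNCQWDDSWEDRSWHHP
>E
RSTCTQNLQMVTLPQEFNNDWCIIFSLRHGQNHVMTCWCVTSEFVQASESEWFETWMSPY
NKSLQVLKTATCFVLSCQMTIHQFQRSFHLRSIGYTQMQDCDMEHYAITDKWDLKCSWGH
HWNDNWILYHIWWVDIESEMGSCPGRDIMKLAKMHKSVISKSEYNYAGQHTKYDYSKCAP
QYLWTRFILWMVCCFTLHA-----------------------------------------
----------PGICMDPKMRDLEEGHCHLWQTCNPLREDAHEACYVKQLKHFFDIQRFLL
SVEHLPRGIAERGDSGYVRQYSIKCMVWVNSKQAQCGVWTNCQWTDGWIDDKQHHN
>F
RSTCKQNLQMRTLPQEFNNLWCIIFSLRHGQGHVMTCWCVTSEFDQASESEWFETWVSPY
NKSLQFLKTATCSVLSCQMTGHQFWRSFHLRSIGYTQMQDQDMEHYAITDKWDLHCSWGH
HWNDNWILYHIWWPDIESEPGSCPGRDIMKLAKMHKSVISKSEYHYAGQHTKYDYSKCAP
QYLWTRFILWMVCCFTLHAAKYCWQVWPCHFHCWYKLQLWEMMPMYSNTNHVNYKFKFKR
VNIYHRDRWSPGICGIEKMRDLEEGHCHCWQTCNPLREDAHAACYVKQLKHHFDIQRFLL
WVEPLPRCSAERGDSGYVRQYSIKCMFWVNWKQAQTGVWTNCQWTDGWIDVKQHHN
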