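<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000001</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2012</Year></PubDate>
          </JournalIssue>
          <Title>Journal of Example Oncology</Title>
        </Journal>
        <ArticleTitle>PTEN and MMAC1 refer to the same tumour suppressor in breast cancer.</ArticleTitle>
        <Abstract>
          <AbstractText>Loss of PTEN expression was observed in tumour samples. ERBB2 (HER2) amplification co-occurred with ESR1 positivity.</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <LastName>Alpha</LastName>
            <ForeName>Ann</ForeName>
            <AffiliationInfo>
              <Affiliation>Department of Computer Science, University of Calgary, Calgary, AB Canada</Affiliation>
            </AffiliationInfo>
          </Author>
          <Author>
            <LastName>Beta</LastName>
            <ForeName>Berk</ForeName>
            <AffiliationInfo>
              <Affiliation>TOBB University, Ankara, Turkey</Affiliation>
            </AffiliationInfo>
          </Author>
        </AuthorList>
      </Article>
      <KeywordList><Keyword>breast cancer</Keyword><Keyword>PTEN</Keyword></KeywordList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000002</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><MedlineDate>1998 Jul-Aug</MedlineDate></PubDate>
          </JournalIssue>
          <Title>Example Reviews</Title>
        </Journal>
        <ArticleTitle>BRCA1 and BRCA2 in hereditary breast cancer.</ArticleTitle>
        <Abstract>
          <AbstractText Label="BACKGROUND">Germline BRCA1 variants confer risk.</AbstractText>
          <AbstractText Label="METHODS">We reviewed BRCA2 carrier cohorts.</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <LastName>Gamma</LastName>
            <ForeName>Gina</ForeName>
            <AffiliationInfo>
              <Affiliation>Institute of Genetics, Heidelberg, Germany</Affiliation>
            </AffiliationInfo>
          </Author>
        </AuthorList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000003</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2005</Year></PubDate>
          </JournalIssue>
          <Title>Letters in Oncology</Title>
        </Journal>
        <ArticleTitle>Comment on screening programmes.</ArticleTitle>
        <AuthorList>
          <Author>
            <LastName>Delta</LastName>
            <ForeName>Dai</ForeName>
          </Author>
        </AuthorList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
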